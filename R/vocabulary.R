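#' Chromosome codes of the tetraploid cotton genome
#'
#' The 26 chromosomes of allotetraploid cotton, coded `c1`..`c26`.
#' Chromosomes c1-c13 belong to the A subgenome and c14-c26 to the D
#' subgenome.
#'
#' @return Character vector of the 26 chromosome codes.
#' @export
#' @examples
#' chromosome_codes()
chromosome_codes <- function() {
  paste0("c", 1:26)
}

#' Controlled vocabulary of cotton QTL trait codes
#'
#' The 43 trait codes used throughout the package, each assigned to exactly
#' one trait category. The codes cover fiber quality (e.g. fiber strength
#' `FS`, fiber length `FL`, micronaire `Micro`), yield and yield components,
#' seed quality, plant morphology, disease/pest resistance, physiology and
#' drought tolerance.
#'
#' @return A tibble with columns `trait` (code) and `category`.
#' @export
#' @examples
#' trait_vocabulary()
trait_vocabulary <- function() {
  fiber <- c("FS", "FL", "Micro", "FU", "FE", "Color", "FM", "Perimeter",
             "WT", "WallThick", "SLF")
  yield <- c("HI", "BW", "LI", "LP", "SCY", "LY", "BN", "LB")
  seed  <- c("Gossypol", "Protein", "Oil", "HP", "EPP", "LargenumFS",
             "NOFuzFib", "SW", "SI", "SM")
  morph <- c("FBNum", "FBNode", "Pubescence", "NFFB", "HNFFB", "LeafMorph")
  resist <- c("Nematode", "VW", "Fusarium", "Xcm")
  physio <- "Chlorophyll"
  drought <- c("OP", "CIR", "CT")
  tibble(
    trait = c(fiber, yield, seed, morph, resist, physio, drought),
    category = rep(
      c("fiber quality", "yield", "seed quality", "morphological",
        "resistance", "physiological", "drought tolerance"),
      times = c(length(fiber), length(yield), length(seed), length(morph),
                length(resist), length(physio), length(drought))
    )
  )
}

# synonym -> canonical code, matched after case-folding and stripping
# spaces/underscores/dashes; covers the spellings seen in source studies
trait_synonyms <- function() {
  c(
    "micronaire"   = "Micro",
    "microanaire"  = "Micro",
    "mic"          = "Micro",
    "wallthick"    = "WallThick",
    "wallthickness" = "WallThick",
    "leafmorph"    = "LeafMorph",
    "leafmorphology" = "LeafMorph",
    "leaf"         = "LeafMorph",
    "lm"           = "LeafMorph",
    "color"        = "Color",
    "colour"       = "Color",
    "fbnum"        = "FBNum",
    "fbnode"       = "FBNode",
    "nematoderelated" = "Nematode",
    "nematode"     = "Nematode",
    "verticillium" = "VW",
    "fusariumwilt" = "Fusarium",
    "chlorophyllcontent" = "Chlorophyll"
  )
}

#' Normalize trait labels to the canonical trait codes
#'
#' Maps free-form trait labels (e.g. `"Micronaire"`, `"Leaf morph"`,
#' `"color"`) to the canonical codes of [trait_vocabulary()]. Matching is
#' case-insensitive and ignores spaces, underscores and dashes. Labels that
#' match neither a code nor a known synonym are returned as `NA`.
#'
#' @param x Character vector of trait labels.
#' @param vocabulary Trait vocabulary tibble, see [trait_vocabulary()].
#' @return Character vector of canonical trait codes (`NA` where unknown).
#' @export
#' @examples
#' normalize_traits(c("Micronaire", "FS", "Leaf morph", "bogus"))
normalize_traits <- function(x, vocabulary = trait_vocabulary()) {
  key <- function(v) gsub("[ _-]", "", tolower(v))
  codes <- vocabulary$trait
  lookup <- c(setNames(codes, key(codes)), trait_synonyms())
  out <- unname(lookup[key(as.character(x))])
  out[is.na(x)] <- NA_character_
  out
}
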