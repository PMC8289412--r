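.adduct_classes <- c("7mG", "3mA", "O6mG", "other")
.nalkyl_classes <- c("7mG", "3mA")
.strands <- c("top", "bottom")

# base required on the lesion-carrying strand for each class (NA = any)
.class_base <- c("7mG" = "G", "3mA" = "A", "O6mG" = "G", "other" = NA)

.complement <- c(A = "T", C = "G", G = "C", T = "A")

# Base at 0-based coordinate `pos` on the given strand. The sequence is the
# top strand 5'->3'; a bottom-strand site at coordinate i pairs with, and is
# the complement of, the top-strand base at i.
strand_base <- function(sequence_chars, pos, strand) {
  b <- sequence_chars[pos + 1L]
  ifelse(strand == "bottom", unname(.complement[b]), b)
}

#' Construct a lesion map
#'
#' A lesion map lists the adducts carried by one plasmid molecule: a 0-based
#' strand-nucleotide position in `[0, length_bp)`, a strand (`"top"` or
#' `"bottom"`) and an adduct class (`"7mG"`, `"3mA"`, `"O6mG"`, `"other"`).
#' At most one lesion may occupy a given (position, strand) site.
#'
#' @param plasmid a [plasmid_spec()].
#' @param position integer vector of 0-based positions.
#' @param strand character vector, `"top"`/`"bottom"`.
#' @param adduct_class character vector of adduct classes.
#' @return a data.frame of class `lesion_map` with attribute `plasmid`.
#' @export
lesion_map <- function(plasmid, position = integer(), strand = character(),
                       adduct_class = character()) {
  stopifnot(inherits(plasmid, "plasmid_spec"))
  n <- length(position)
  if (length(strand) != n || length(adduct_class) != n)
    stop_bad("position, strand and adduct_class must have equal length")
  position <- as.integer(position)
  if (n > 0) {
    if (any(position < 0L | position >= plasmid$length_bp))
      stop_bad("lesion positions must lie in [0, ", plasmid$length_bp, ")")
    if (!all(strand %in% .strands))
      stop_bad("strand must be 'top' or 'bottom'")
    if (!all(adduct_class %in% .adduct_classes))
      stop_bad("adduct_class must be one of: ",
               paste(.adduct_classes, collapse = ", "))
    if (anyDuplicated(paste(position, strand)))
      stop_bad("at most one lesion per (position, strand) site")
  }
  out <- data.frame(position = position, strand = as.character(strand),
                    adduct_class = as.character(adduct_class),
                    stringsAsFactors = FALSE)
  attr(out, "plasmid") <- plasmid
  class(out) <- c("lesion_map", "data.frame")
  out
}

#' Randomly place alkylation adducts on a plasmid
#'
#' Every strand-nucleotide (there are `2 * length_bp` of them) independently
#' carries an adduct with probability equal to the *total* adduct density,
#' `nalkyl_density / (frac_7mG + frac_3mA)`; classes are then drawn from the
#' spectrum. `nalkyl_density` is expressed as N-alkyl (7mG + 3mA) adducts
#' per strand-nucleotide because that is what the alkaline-cleavage
#' calibration assay measures. In sequence-aware mode, lesions whose class
#' is incompatible with the base at the drawn site (7mG and O6mG require G
#' on their strand, 3mA requires A) are re-positioned by rejection: the
#' class and strand are kept and a new position is drawn. This preserves
#' class proportions but locally re-weights density on skewed base
#' compositions.
#'
#' @param plasmid a [plasmid_spec()].
#' @param nalkyl_density N-alkyl adducts per strand-nucleotide, in `[0, 0.5]`.
#' @param spectrum an [adduct_spectrum()].
#' @param seed optional integer seed (sets the global RNG).
#' @param sequence_aware place classes only on compatible bases; requires
#'   `plasmid$sequence`.
#' @return a [lesion_map()].
#' @export
#' @examples
#' m <- place_lesions(plasmid("pBR322"), 1 / 500, spectrum_for_agent("MNU"),
#'                    seed = 1)
#' table(m$adduct_class)
place_lesions <- function(plasmid, nalkyl_density, spectrum, seed = NULL,
                          sequence_aware = FALSE) {
  stopifnot(inherits(plasmid, "plasmid_spec"),
            inherits(spectrum, "adduct_spectrum"))
  check_number(nalkyl_density, "nalkyl_density", lower = 0, upper = 0.5)
  check_flag(sequence_aware, "sequence_aware")
  if (sequence_aware && is.null(plasmid$sequence))
    stop_bad("sequence-aware placement requires a plasmid sequence")
  fN <- spectrum$frac_7mG + spectrum$frac_3mA
  if (fN <= 0 && nalkyl_density > 0)
    stop_bad("spectrum has no N-alkyl fraction; cannot anchor density")
  p_total <- if (nalkyl_density == 0) 0 else nalkyl_density / fN
  if (p_total > 1)
    stop_bad("total adduct density exceeds 1 per strand-nucleotide")
  if (!is.null(seed)) set.seed(seed)

  L <- plasmid$length_bp
  fracs <- c(spectrum$frac_7mG, spectrum$frac_3mA, spectrum$frac_O6mG,
             spectrum$frac_other)
  pos <- integer(); str <- character(); cls <- character()
  for (s in .strands) {
    k <- rbinom(1L, L, p_total)
    if (k > 0) {
      pos <- c(pos, sample.int(L, k) - 1L)
      str <- c(str, rep(s, k))
      cls <- c(cls, sample(.adduct_classes, k, replace = TRUE, prob = fracs))
    }
  }

  if (sequence_aware && length(pos) > 0) {
    chars <- strsplit(plasmid$sequence, "")[[1]]
    need <- unname(.class_base[cls])
    for (i in seq_along(pos)) {
      if (is.na(need[i])) next
      tries <- 0L
      while (strand_base(chars, pos[i], str[i]) != need[i] ||
             any(pos[-i][str[-i] == str[i]] == pos[i])) {
        pos[i] <- sample.int(L, 1L) - 1L
        tries <- tries + 1L
        if (tries > 100L * L)
          stop_bad("no compatible base available for class ", cls[i],
                   " on strand ", str[i])
      }
    }
  }

  lesion_map(plasmid, pos, str, cls)
}

#' Expected per-class adduct counts (closed-form twin of [place_lesions()])
#'
#' @inheritParams place_lesions
#' @return a list with `nalkyl` (expected 7mG + 3mA count), `o6mg`
#'   (`nalkyl / no_ratio(spectrum)`), `total` and a named per-class vector
#'   `by_class`.
#' @export
#' @examples
#' sp <- adduct_spectrum(0.75, 0.15, 0.09, 0.01) # N:O ratio 10
#' expected_counts(plasmid("pBR322"), 1 / 500, sp)$o6mg # 1.72
expected_counts <- function(plasmid, nalkyl_density, spectrum) {
  stopifnot(inherits(plasmid, "plasmid_spec"),
            inherits(spectrum, "adduct_spectrum"))
  check_number(nalkyl_density, "nalkyl_density", lower = 0, upper = 0.5)
  fN <- spectrum$frac_7mG + spectrum$frac_3mA
  if (fN <= 0 && nalkyl_density > 0)
    stop_bad("spectrum has no N-alkyl fraction; cannot anchor density")
  nalkyl <- 2 * plasmid$length_bp * nalkyl_density
  total <- if (nalkyl_density == 0) 0 else nalkyl / fN
  by_class <- total * c(`7mG` = spectrum$frac_7mG, `3mA` = spectrum$frac_3mA,
                        O6mG = spectrum$frac_O6mG, other = spectrum$frac_other)
  list(nalkyl = nalkyl, o6mg = if (total == 0) 0 else nalkyl / no_ratio(spectrum),
       total = total, by_class = by_class)
}
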