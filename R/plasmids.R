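#' Describe a plasmid substrate
#'
#' A `plasmid_spec` records the minimal geometry the simulator needs: a
#' name, the length in base pairs, circularity, and optionally the top
#' strand sequence (5'->3', IUPAC letters) when sequence-aware lesion
#' placement is wanted. A plasmid of `length_bp` base pairs exposes
#' `2 * length_bp` strand-nucleotides to alkylation.
#'
#' @param name plasmid name.
#' @param length_bp length in base pairs (> 0).
#' @param circular logical; all stock plasmids are circular.
#' @param sequence optional character scalar, the top-strand sequence; its
#'   number of characters must equal `length_bp`.
#' @return an object of class `plasmid_spec`.
#' @seealso [plasmid()] for the registry of stock plasmids.
#' @export
#' @examples
#' plasmid_spec("pUC-like", 2686)
plasmid_spec <- function(name, length_bp, circular = TRUE, sequence = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_bad("name must be a non-empty string")
  check_number(length_bp, "length_bp", lower = 1)
  length_bp <- as.integer(round(length_bp))
  check_flag(circular, "circular")
  if (!is.null(sequence)) {
    if (!is.character(sequence) || length(sequence) != 1L)
      stop_bad("sequence must be a single string")
    sequence <- toupper(sequence)
    if (nchar(sequence) != length_bp)
      stop_bad("sequence length (", nchar(sequence),
               ") does not match length_bp (", length_bp, ")")
    bad <- gsub("[ACGTRYSWKMBDHVN]", "", sequence)
    if (nzchar(bad))
      stop_bad("sequence contains non-IUPAC characters: ",
               paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  }
  structure(list(name = name, length_bp = length_bp, circular = circular,
                 sequence = sequence),
            class = "plasmid_spec")
}

#' @export
print.plasmid_spec <- function(x, ...) {
  cat(sprintf("<plasmid_spec> %s: %d bp, %s%s\n", x$name, x$length_bp,
              if (x$circular) "circular" else "linear",
              if (is.null(x$sequence)) "" else ", with sequence"))
  invisible(x)
}

# Stock plasmids, nominal lengths from the substrate table (kb x 1000).
.plasmid_registry <- list(
  pAS200.2 = c(length_bp = 2100),
  pBR322   = c(length_bp = 4300),
  pAS04    = c(length_bp = 6500),
  pEL97    = c(length_bp = 11300)
)

#' Stock plasmid substrates
#'
#' `plasmid()` returns one of the four stock circular plasmids by name
#' (pAS200.2 2.1 kb, pBR322 4.3 kb, pAS04 6.5 kb, pEL97 11.3 kb), using
#' their nominal catalogue lengths. `plasmids()` lists the registry.
#' Sequences are not bundled; supply one via [plasmid_spec()] or
#' [load_plasmid_fasta()] when sequence-aware placement is needed.
#'
#' @param name one of `"pAS200.2"`, `"pBR322"`, `"pAS04"`, `"pEL97"`.
#' @return `plasmid()`: a [plasmid_spec()]; `plasmids()`: a data.frame.
#' @export
#' @examples
#' plasmid("pEL97")
plasmid <- function(name) {
  if (!name %in% names(.plasmid_registry))
    stop_bad("unknown plasmid '", name, "'; registered: ",
             paste(names(.plasmid_registry), collapse = ", "))
  plasmid_spec(name, .plasmid_registry[[name]][["length_bp"]],
               circular = TRUE)
}

#' @rdname plasmid
#' @export
plasmids <- function() {
  data.frame(name = names(.plasmid_registry),
             length_bp = vapply(.plasmid_registry, `[[`, numeric(1),
                                "length_bp"),
             circular = TRUE, row.names = NULL)
}
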