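# Run configuration, file I/O and pipeline drivers.

#' Read a plasmid from a single-record FASTA file
#'
#' @param path path to a FASTA file containing exactly one record.
#' @param circular is the plasmid circular (default TRUE).
#' @param name plasmid name; defaults to the FASTA record name.
#' @return a [plasmid_spec()] carrying the sequence.
#' @export
load_plasmid_fasta <- function(path, circular = TRUE, name = NULL) {
  if (!file.exists(path)) stop_bad("FASTA file not found: ", path)
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop_bad("load_plasmid_fasta requires the Biostrings package")
  # Biostrings drops invalid letters with a warning; treat that as an error
  seqs <- withCallingHandlers(
    tryCatch(Biostrings::readDNAStringSet(path),
             error = function(e)
               stop_bad("invalid FASTA (", conditionMessage(e), ")")),
    warning = function(w) stop_bad("invalid FASTA (", conditionMessage(w), ")"))
  if (length(seqs) != 1L)
    stop_bad("expected a single-record FASTA, found ", length(seqs),
             " records")
  s <- as.character(seqs[[1L]])
  if (!nzchar(s)) stop_bad("empty sequence in FASTA")
  plasmid_spec(name %||% sub("\\s.*$", "", names(seqs)[1L]),
               nchar(s), circular = circular, sequence = s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_keys <- c("plasmid", "fasta", "circular", "agent", "spectrum",
                  "doses_mM", "densities", "density_per_mM", "params",
                  "n_molecules", "seed", "out_dir",
                  "target_linear_fraction", "genome", "linear_fraction",
                  "plasmid_bp", "dose_ref_mM", "dose_new_mM")

.plasmid_keys <- c("name", "length_bp", "circular", "sequence")
.genome_keys <- c("n_oalkyl", "n_nalkyl", "genome_nt_for_density",
                  "genome_bp_for_scaling", "window_nt")
.spectrum_keys <- c("frac_7mG", "frac_3mA", "frac_O6mG", "frac_other",
                    "agent")

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop_bad("unknown key(s) in ", where, ": ",
             paste(extra, collapse = ", "),
             "; allowed: ", paste(allowed, collapse = ", "))
}

#' Load and validate a JSON run configuration
#'
#' The configuration resolves, with full validation before any sampling:
#' a plasmid (registry `plasmid` name, inline `plasmid` object, or `fasta`
#' path), an adduct `spectrum` (inline object or registered `agent`),
#' `doses_mM` or direct `densities`, an optional `density_per_mM`
#' calibration, [repair_params()] overrides under `params`, `n_molecules`
#' and `seed`. Unknown keys are rejected with their path.
#'
#' @param path path to a JSON file.
#' @return a list of class `run_config` with resolved `plasmid`, `spectrum`,
#'   `params`, `cal` objects and the raw config under `raw`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop_bad("config file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  check_keys(raw, .config_keys, "config")

  plas <- NULL
  if (!is.null(raw$fasta)) {
    plas <- load_plasmid_fasta(raw$fasta, circular = raw$circular %||% TRUE)
  } else if (is.character(raw$plasmid)) {
    plas <- plasmid(raw$plasmid)
  } else if (is.list(raw$plasmid)) {
    check_keys(raw$plasmid, .plasmid_keys, "config$plasmid")
    plas <- plasmid_spec(raw$plasmid$name %||% "custom",
                         raw$plasmid$length_bp,
                         circular = raw$plasmid$circular %||% TRUE,
                         sequence = raw$plasmid$sequence)
  }

  spec <- if (!is.null(raw$spectrum)) {
    check_keys(raw$spectrum, .spectrum_keys, "config$spectrum")
    adduct_spectrum(raw$spectrum$frac_7mG, raw$spectrum$frac_3mA,
                    raw$spectrum$frac_O6mG, raw$spectrum$frac_other,
                    agent = raw$spectrum$agent %||% "custom")
  } else if (!is.null(raw$agent)) {
    spectrum_for_agent(raw$agent)
  } else {
    spectrum_for_agent("MNU")
  }

  params <- do.call(repair_params, as.list(raw$params %||% list()))
  cal <- dose_calibration(raw$density_per_mM %||% (1 / 500))

  structure(list(plasmid = plas, spectrum = spec, params = params,
                 cal = cal, n_molecules = raw$n_molecules %||% 10000L,
                 seed = raw$seed %||% 1L, out_dir = raw$out_dir %||% ".",
                 raw = raw),
            class = "run_config")
}

write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  path
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

run_manifest <- function(config, subcommand, outputs) {
  list(subcommand = subcommand,
       package = "alkrepair",
       version = as.character(packageVersion("alkrepair")),
       seed = config$seed,
       config = config$raw,
       outputs = basename(unlist(outputs)))
}

#' Execute a configured pipeline stage
#'
#' Subcommands: `"simulate"` (batch Monte Carlo at the first configured
#' dose/density; per-molecule TSV + summary JSON), `"dose-response"`
#' (sweep + quadratic fit), `"fragment-assay"` (lesion placement + alkaline
#' cleavage; fragment-length TSV + density estimates), `"calibrate"`
#' (invert the open-nick probability for `target_linear_fraction`) and
#' `"extrapolate"` (deterministic genome chain). Every run writes a
#' `manifest.json` (config echo, seed, package version) sufficient to
#' reproduce the outputs bit-identically; stage timings are reported via
#' `message()`.
#'
#' @param config a [load_run_config()] object.
#' @param subcommand one of simulate, dose-response, fragment-assay,
#'   calibrate, extrapolate.
#' @param out_dir output directory (created if needed); defaults to the
#'   config's `out_dir`.
#' @return invisibly, a named list of the files written.
#' @export
run <- function(config,
                subcommand = c("simulate", "dose-response", "fragment-assay",
                               "calibrate", "extrapolate"),
                out_dir = config$out_dir) {
  subcommand <- match.arg(subcommand)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  outputs <- list()
  raw <- config$raw

  density_of <- function() {
    if (!is.null(raw$densities)) raw$densities[1]
    else dose_to_density(raw$doses_mM[1] %||% 1, config$cal)
  }

  if (subcommand == "simulate") {
    b <- batch_simulate(config$plasmid, density_of(), config$spectrum,
                        config$params, config$n_molecules,
                        seed = config$seed)
    outputs$molecules <- write_tsv(b$molecules,
                                   file.path(out_dir, "molecules.tsv"))
    s <- b[c("n", "counts", "fractions", "se", "mean_dsb",
             "mean_synthesized_nt", "uds_percent_replication",
             "linear_of_open")]
    s$fractions <- as.list(s$fractions); s$se <- as.list(s$se)
    s$counts <- as.list(s$counts)
    outputs$summary <- write_json(s, file.path(out_dir, "summary.json"))
  } else if (subcommand == "dose-response") {
    doses <- raw$doses_mM %||% stop_bad("dose-response requires doses_mM")
    pts <- sweep_doses(doses, config$plasmid, config$spectrum,
                       config$params, config$n_molecules,
                       seed = config$seed, cal = config$cal)
    outputs$points <- write_tsv(pts, file.path(out_dir, "points.tsv"))
    if (nrow(pts) >= 2 && var(pts$dose_mM^2) > 0) {
      fit <- fit_linear_fraction_vs_dose_squared(pts)
      outputs$fit <- write_json(unclass(fit), file.path(out_dir, "fit.json"))
    }
  } else if (subcommand == "fragment-assay") {
    set.seed(config$seed)
    maps <- replicate(config$n_molecules,
                      place_lesions(config$plasmid, density_of(),
                                    config$spectrum),
                      simplify = FALSE)
    prof <- cleave_at_nalkyl(maps)
    outputs$fragments <- write_tsv(prof$fragments,
                                   file.path(out_dir, "fragments.tsv"))
    med <- prof$median_nt
    outputs$summary <- write_json(
      list(n_molecules = prof$n_molecules,
           mean_nicks_per_strand = prof$mean_nicks_per_strand,
           median_fragment_nt = med,
           density_paper_mode = if (is.na(med)) NA else
             estimate_density_from_median(med, "paper"),
           density_geometric_mode = if (is.na(med)) NA else
             estimate_density_from_median(med, "geometric")),
      file.path(out_dir, "fragment_summary.json"))
  } else if (subcommand == "calibrate") {
    target <- raw$target_linear_fraction %||%
      stop_bad("calibrate requires target_linear_fraction")
    p <- calibrate_nick_availability(target, config$plasmid, density_of(),
                                     config$spectrum, config$params)
    outputs$calibration <- write_json(
      list(target_linear_fraction = target, p_nick_open = p),
      file.path(out_dir, "calibration.json"))
  } else if (subcommand == "extrapolate") {
    g <- raw$genome %||% list()
    check_keys(g, .genome_keys, "config$genome")
    load <- do.call(genome_lesion_load, g)
    est <- genome_estimate(load,
                           linear_fraction = raw$linear_fraction %||% 0.06,
                           plasmid_bp = raw$plasmid_bp %||% 11300,
                           dose_ref_mM = raw$dose_ref_mM %||% 2,
                           dose_new_mM = raw$dose_new_mM %||% 0.05)
    outputs$estimate <- write_json(unclass(est),
                                   file.path(out_dir, "extrapolation.json"))
  }

  outputs$manifest <- write_json(run_manifest(config, subcommand, outputs),
                                 file.path(out_dir, "manifest.json"))
  message(sprintf("[alkrepair] %s completed in %.2f s (%d file(s) written)",
                  subcommand, proc.time()[["elapsed"]] - t0,
                  length(outputs)))
  invisible(outputs)
}
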