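#' Run configuration for the epitope-mapping analyses
#'
#' Collects and validates the shared parameters of the pipeline. The
#' defaults are the reference constants of the analysis: allowed residues
#' MKPLTGVEF (the reference peptide's unique residues less its NNI
#' suffix), excluded residues ARNDCQHISWY, short-protein threshold 100
#' residues, big-difference threshold 10 squared angstroms, confidence
#' level 0.995.
#'
#' @param motif Core motif string.
#' @param sub_patterns Sub-patterns to tally.
#' @param window_pattern Anchored window pattern.
#' @param allowed_residues Allowed residue set (canonical letters only).
#' @param excluded_residues Excluded residue set (canonical letters only).
#' @param short_threshold Short-protein threshold (> 0).
#' @param big_diff_threshold Big-difference threshold in squared angstroms
#'   (> 0).
#' @param confidence Confidence level in (0, 1).
#' @param t_variant t-test variant, `"pooled"` or `"welch"`.
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(motif = "NNI",
                       sub_patterns = c("FNNI", "EFNNI"),
                       window_pattern = "M..........NNI",
                       allowed_residues = "MKPLTGVEF",
                       excluded_residues = "ARNDCQHISWY",
                       short_threshold = 100,
                       big_diff_threshold = 10,
                       confidence = 0.995,
                       t_variant = c("pooled", "welch"),
                       seed = 1,
                       out_dir = "results") {
  t_variant <- match.arg(t_variant)
  check_residues <- function(s, what) {
    ch <- strsplit(toupper(s), "")[[1]]
    bad <- setdiff(ch, AA_CANONICAL)
    if (length(bad) > 0) {
      stop("invalid residue '", paste(bad, collapse = "', '"),
           "' in ", what)
    }
    paste(ch, collapse = "")
  }
  allowed_residues <- check_residues(allowed_residues, "allowed_residues")
  excluded_residues <- check_residues(excluded_residues, "excluded_residues")
  if (!(short_threshold > 0)) stop("short_threshold must be positive")
  if (!(big_diff_threshold > 0)) stop("big_diff_threshold must be positive")
  if (!(confidence > 0 && confidence < 1)) {
    stop("confidence must lie in (0, 1)")
  }
  structure(list(
    motif = motif, sub_patterns = sub_patterns,
    window_pattern = window_pattern,
    allowed_residues = allowed_residues,
    excluded_residues = excluded_residues,
    short_threshold = as.integer(short_threshold),
    big_diff_threshold = big_diff_threshold,
    confidence = confidence, t_variant = t_variant,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "run_config")
}

#' Read a run configuration from a flat YAML key-value file
#'
#' Keys present in the file override the defaults; `overrides` (e.g.
#' command-line flags) take precedence over both.
#'
#' @param path YAML file path, or `NULL` for defaults only.
#' @param overrides Named list overriding file values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- yaml::read_yaml(path)
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}

#' Write a run configuration to YAML
#'
#' @param config A `run_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write a run manifest recording inputs, parameters and seed
#'
#' @param config A `run_config`.
#' @param inputs Named character vector/list of input paths.
#' @param path Output YAML path (default `run_manifest.yaml` under the
#'   config's output directory).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(config, inputs = list(),
                               path = file.path(config$out_dir,
                                                "run_manifest.yaml")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("nniomics")),
    seed = config$seed,
    inputs = as.list(inputs),
    parameters = unclass(config)
  ), path)
  invisible(path)
}
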