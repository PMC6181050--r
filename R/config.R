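# Configuration: documented defaults, a plain key=value file format, and
# CLI-style overrides. The resolved configuration is echoed into every TSV
# report header.

.CONFIG_DEFAULTS <- list(
  linker = "DSS",               # cross-linker chemistry
  precursor_ppm = 10,           # precursor mass tolerance (ppm)
  frag_da = 0.05,               # fragment tolerance, absolute (Da)
  frag_ppm = 10,                # fragment tolerance, relative (ppm)
  e_max = 0.01,                 # step-1 E-value acceptance threshold
  max_missed = 3L,              # missed cleavages (linked K blocks cleavage)
  min_pep_len = 4L,             # shortest searched peptide (residues)
  max_pep_len = 60L,            # longest searched peptide (residues)
  max_precursor_charge = 6L,    # precursors above this are skipped
  max_fragment_charge = NA_integer_,  # NA: precursor charge - 1
  oxidize_met = TRUE,           # Met oxidation as only variable modification
  validate_mode = "top",        # "top": step-1 hit must stay top-ranked;
                                # "factor": within validate_factor of best
  validate_factor = 1,
  restraint_threshold = 30,     # C-alpha distance limit (Angstrom)
  reference_subunit = "PSAF",   # stoichiometry normalization reference
  seed = 1L
)

.coerce_like <- function(value, template, key) {
  out <- switch(class(template)[1L],
    integer = suppressWarnings(as.integer(value)),
    numeric = suppressWarnings(as.numeric(value)),
    logical = as.logical(toupper(value)),
    as.character(value))
  if (length(out) != 1L || (is.na(out) && !is.na(template) &&
                            toupper(value) != "NA"))
    stop("unparsable value for config key ", key, ": ", value, call. = FALSE)
  out
}

#' Load the run configuration
#'
#' Resolves the configuration in three layers: documented defaults, then a
#' plain `key=value` file, then explicit overrides (e.g. CLI flags). Unknown
#' keys and unparsable values are errors.
#'
#' @param path Optional path to a `key=value` file (`#` comments allowed).
#' @param overrides Named list of values overriding file and defaults.
#' @return A named list of class `xl_config`.
#' @examples
#' cfg <- load_config(overrides = list(e_max = 0.05))
#' cfg$e_max
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- .CONFIG_DEFAULTS
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[nzchar(trimws(lines))])
    for (ln in lines) {
      if (!grepl("=", ln, fixed = TRUE))
        stop("unparsable config line: ", ln, call. = FALSE)
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (!key %in% names(cfg))
        stop("unknown config key: ", key, call. = FALSE)
      cfg[[key]] <- .coerce_like(val, cfg[[key]], key)
    }
  }
  for (key in names(overrides)) {
    if (!key %in% names(cfg))
      stop("unknown config key: ", key, call. = FALSE)
    cfg[[key]] <- .coerce_like(as.character(overrides[[key]]), cfg[[key]],
                               key)
  }
  structure(cfg, class = "xl_config")
}

#' Write a configuration to a key=value file
#'
#' Round-trips with [load_config()].
#'
#' @param config An `xl_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  writeLines(sprintf("%s=%s", names(config),
                     vapply(config, as.character, character(1L))), path)
  invisible(path)
}

#' @export
print.xl_config <- function(x, ...) {
  cat("<xl_config>\n")
  for (k in names(x)) cat(sprintf("  %s = %s\n", k, as.character(x[[k]])))
  invisible(x)
}
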