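# Shared report writing: TSV with '#'-prefixed provenance headers echoing
# the resolved configuration, so every output records the parameters that
# produced it. Headers carry no timestamps: identical inputs and
# configuration must give byte-identical files.

#' Write a result table as TSV with provenance headers
#'
#' @param df A data.frame.
#' @param path Output path.
#' @param config Optional `xl_config` echoed into `#` header lines.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# xlscout %s",
                     as.character(utils::packageVersion("xlscout"))), con)
  if (!is.null(config))
    writeLines(sprintf("# %s=%s", names(config),
                       vapply(config, as.character, character(1L))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
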