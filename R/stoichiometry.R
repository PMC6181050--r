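# Subunit stoichiometry from uniform 14C gel densitometry. A uniformly
# labeled protein's band signal is proportional to (molar copies) x (carbon
# atoms), so dividing by the carbon number yields relative molar amounts.
# Subunits unresolved in the reference gel system are recovered by
# calibrating a second system against a comigrated band, or by partitioning
# a composite band with spot ratios from a third (2D) system.

#' Convert a densitometry signal to relative molar units
#'
#' @param signal Band signal(s), arbitrary units >= 0.
#' @param carbons Carbon count(s) of the corresponding polypeptide (> 0).
#' @return `signal / carbons`.
#' @export
molar_signal <- function(signal, carbons) {
  if (any(carbons <= 0)) stop("carbon count must be > 0", call. = FALSE)
  signal / carbons
}

#' Effective carbon number of a comigrated band
#'
#' A band containing several subunits at (relative) molar amounts `weights`
#' has signal proportional to `sum(weights * carbons)`; its molar content is
#' `sum(weights)`. The effective carbon number — the value by which the band
#' signal must be divided so that signal/carbon equals total molar content —
#' is the abundance-weighted mean carbon count.
#'
#' @param carbons Carbon counts of the band members.
#' @param weights Relative molar abundances of the members (e.g. estimates
#'   from the reference gel system).
#' @return `sum(weights * carbons) / sum(weights)`.
#' @export
effective_carbon <- function(carbons, weights) {
  stopifnot(length(carbons) == length(weights), all(weights >= 0),
            sum(weights) > 0)
  sum(weights * carbons) / sum(weights)
}

#' Calibrate a gel system against a comigrated reference band
#'
#' When two subunits resolved individually in the reference system comigrate
#' as one band in a second system, the second system's overall gain is fixed
#' by requiring the comigrated band's molar value to equal the sum of the
#' two reference abundances.
#'
#' @param comigrated_value Molar value of the comigrated band in the second
#'   system (band signal divided by its [effective_carbon()]).
#' @param reference_sum Sum of the members' abundances from the reference
#'   system.
#' @return The scale factor `reference_sum / comigrated_value` to apply to
#'   every molar value of the second system.
#' @examples
#' calibrate_comigrated(2.17, 2.17)  # 1
#' @export
calibrate_comigrated <- function(comigrated_value, reference_sum) {
  if (comigrated_value <= 0)
    stop("comigrated band value must be > 0", call. = FALSE)
  reference_sum / comigrated_value
}

#' Partition a composite band's molar total across its members
#'
#' @param total_molar Total molar content of the composite band(s).
#' @param fractions Named molar fractions of the members (carbon-normalized
#'   spot ratios from the partitioning system); must sum to 1.
#' @return Named per-member molar values `total_molar * fractions`.
#' @export
partition_composite <- function(total_molar, fractions) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1", call. = FALSE)
  total_molar * fractions
}

#' Read a gel band table
#'
#' @param path TSV with columns `gel_system`, `band_label`, `members`
#'   (semicolon-separated subunit ids), `signal`, `replicate`.
#' @return The band data.frame.
#' @export
read_band_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gel_system", "band_label", "members", "signal", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("band table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(df$signal < 0)) stop("negative band signal", call. = FALSE)
  df
}

.members <- function(s) strsplit(s, ";", fixed = TRUE)[[1L]]

# Resolve one replicate of one band table into abundances relative to the
# reference subunit. Three routes, in order:
#   A  single-member band in the reference system (the system that resolves
#      the reference subunit as a single band);
#   B  single-member band in a system calibrated through a comigrated band
#      whose members all have route-A values;
#   C  member of reference-system composite band(s) partitioned by
#      single-member spot signals from another system.
.integrate_one <- function(bands, carbons, reference) {
  cn <- function(id) {
    v <- carbons[id]
    if (any(is.na(v))) stop("no carbon count for subunit(s): ",
                            paste(id[is.na(v)], collapse = ", "),
                            call. = FALSE)
    v
  }
  mem <- lapply(bands$members, .members)
  single <- lengths(mem) == 1L
  ref_row <- single & vapply(mem, function(m) m[1L] == reference, logical(1L))
  if (!any(ref_row))
    stop("reference subunit ", reference,
         " is not a single band in any gel system", call. = FALSE)
  ref_system <- bands$gel_system[which(ref_row)[1L]]

  abundance <- c(); route <- c()
  # route A
  in_ref <- bands$gel_system == ref_system
  ref_molar <- NULL
  for (i in which(in_ref & single)) {
    id <- mem[[i]][1L]
    if (id %in% names(abundance)) next
    abundance[id] <- molar_signal(bands$signal[i], cn(id))
    route[id] <- "direct"
  }
  abundance <- abundance / abundance[reference]

  # route B: other systems with single bands, calibrated via a comigrated
  # band fully resolved in the reference system
  for (sys in setdiff(unique(bands$gel_system), ref_system)) {
    rows <- which(bands$gel_system == sys)
    calib <- rows[!single[rows] &
                    vapply(mem[rows], function(m)
                      all(m %in% names(abundance)[route == "direct"]),
                      logical(1L))]
    if (length(calib) == 0L) next
    i <- calib[[1L]]
    w <- abundance[mem[[i]]]
    band_value <- molar_signal(bands$signal[i],
                               effective_carbon(cn(mem[[i]]), w))
    scale <- calibrate_comigrated(band_value, sum(w))
    for (j in rows[single[rows]]) {
      id <- mem[[j]][1L]
      if (id %in% names(abundance)) next
      abundance[id] <- molar_signal(bands$signal[j], cn(id)) * scale
      route[id] <- paste0("calibrated:", sys)
    }
  }

  # route C: unresolved members of reference-system composite bands,
  # partitioned by single-member spots from another system
  comp_rows <- which(in_ref & !single)
  unresolved <- setdiff(unique(unlist(mem[comp_rows])), names(abundance))
  if (length(unresolved) > 0L) {
    grp_rows <- comp_rows[vapply(mem[comp_rows], function(m)
      any(m %in% unresolved), logical(1L))]
    group <- unique(unlist(mem[grp_rows]))
    # the partitioning system must resolve every group member as a spot
    part_sys <- NULL
    for (sys in setdiff(unique(bands$gel_system), ref_system)) {
      rows <- which(bands$gel_system == sys & single)
      ids <- vapply(mem[rows], `[`, character(1L), 1L)
      if (all(group %in% ids)) { part_sys <- sys; break }
    }
    if (is.null(part_sys))
      stop("no resolution route for subunit(s): ",
           paste(unresolved, collapse = ", "), call. = FALSE)
    rows <- which(bands$gel_system == part_sys & single)
    ids <- vapply(mem[rows], `[`, character(1L), 1L)
    spot <- bands$signal[rows][match(group, ids)]
    # split the composite SIGNAL by raw spot-signal fractions, then
    # carbon-normalize each share (a band signal is carbon-weighted)
    total_signal <- sum(bands$signal[grp_rows])
    ref_signal <- bands$signal[which(in_ref & ref_row)[1L]]
    share <- total_signal * spot / sum(spot)
    val <- molar_signal(share, cn(group)) /
      molar_signal(ref_signal, cn(reference))
    for (k in seq_along(group)) {
      id <- group[k]
      if (id %in% names(abundance)) next
      abundance[id] <- val[k]
      route[id] <- paste0("partitioned:", part_sys)
    }
  }
  list(abundance = abundance, route = route)
}

#' Integrate replicated gel band tables into subunit abundances
#'
#' Resolves every subunit per replicate (direct quantification in the
#' reference system, comigration-calibrated second system, or composite-band
#' partition), normalizes to the reference subunit, then summarizes across
#' replicates as mean and standard error (sample sd / sqrt(n)). Copy numbers
#' are the means rounded to the nearest integer (ties away from zero); a
#' mean whose fractional part falls in [0.4, 0.6] triggers a warning.
#'
#' @param bands A band data.frame ([read_band_table()]) covering all
#'   replicates.
#' @param carbons Named vector of carbon counts per subunit (e.g. from
#'   [carbon_count()] on mature sequences).
#' @param reference Reference subunit id (abundance fixed at 1).
#' @return A data.frame with columns `subunit`, `mean`, `se`, `n`, `copies`,
#'   `route`, with attribute `total_lhci` (sum of rounded copies over
#'   subunits whose id starts with "LHCA").
#' @export
integrate_stoichiometry <- function(bands, carbons, reference = "PSAF") {
  reps <- sort(unique(bands$replicate))
  per <- lapply(reps, function(r)
    .integrate_one(bands[bands$replicate == r, , drop = FALSE],
                   carbons, reference))
  ids <- unique(unlist(lapply(per, function(p) names(p$abundance))))
  mat <- sapply(per, function(p) p$abundance[ids])
  mat <- matrix(mat, nrow = length(ids),
                dimnames = list(ids, NULL))
  mn <- rowMeans(mat)
  se <- if (ncol(mat) > 1L) apply(mat, 1L, stats::sd) / sqrt(ncol(mat))
        else rep(0, length(ids))
  cp <- sign(mn) * floor(abs(mn) + 0.5)         # ties away from zero
  fr <- abs(mn - trunc(mn))
  amb <- fr >= 0.4 & fr <= 0.6
  if (any(amb))
    warning("copy number ambiguous (fractional part in [0.4, 0.6]) for: ",
            paste(ids[amb], collapse = ", "), call. = FALSE)
  out <- data.frame(subunit = ids, mean = unname(mn), se = unname(se),
                    n = ncol(mat), copies = as.integer(cp),
                    route = unname(per[[1L]]$route[ids]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$subunit), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_lhci") <- sum(out$copies[startsWith(out$subunit, "LHCA")])
  out
}
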