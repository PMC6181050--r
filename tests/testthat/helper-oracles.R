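# Brute-force oracles, independent of the implementation paths they check.

# Trypsin rule: positions after which cleavage occurs (K/R not before P).
oracle_cleavage_sites <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (n < 2L) return(integer())
  which(ch[-n] %in% c("K", "R") & ch[-1L] != "P")
}

# Enumerate every substring; keep those whose boundaries are valid cleavage
# boundaries with <= max_missed internal sites and length within bounds.
oracle_digest <- function(s, max_missed, min_len = 1L, max_len = 1000L) {
  sites <- oracle_cleavage_sites(s)
  n <- nchar(s)
  out <- NULL
  for (i in seq_len(n)) for (j in i:n) {
    if (!(i == 1L || (i - 1L) %in% sites)) next
    if (!(j == n || j %in% sites)) next
    internal <- sum(sites >= i & sites < j)
    if (internal > max_missed) next
    len <- j - i + 1L
    if (len < min_len || len > max_len) next
    out <- rbind(out, data.frame(start = i, end = j,
                                 sequence = substr(s, i, j),
                                 missed_cleavages = internal,
                                 stringsAsFactors = FALSE))
  }
  out[order(out$start, out$end), , drop = FALSE]
}

# All unordered linkable pairs matching an observed mass within tol_ppm of
# the theoretical mass.
oracle_pairs <- function(index, observed, bridge, tol_ppm) {
  ok <- which(index$n_sites > 0L)
  out <- NULL
  for (a in ok) for (b in ok) {
    if (b < a) next
    theo <- index$mass[a] + index$mass[b] + bridge
    if (abs(theo - observed) / theo <= tol_ppm * 1e-6)
      out <- rbind(out, data.frame(a = a, b = b, theo = theo))
  }
  out
}

# Fragment masses of a cross-linked pair from first principles: every
# prefix/suffix mass computed via peptide_mono_mass on substrings, shifted
# by bridge + full partner mass when the piece covers the linked residue.
oracle_fragments <- function(seq_a, link_a, seq_b, link_b, bridge) {
  water <- mass_constants()$water
  one <- function(s, link, partner_mass) {
    n <- nchar(s)
    masses <- numeric()
    for (i in seq_len(n - 1L)) {
      b <- peptide_mono_mass(substr(s, 1L, i)) - water
      if (i >= link) b <- b + bridge + partner_mass
      y <- peptide_mono_mass(substr(s, n - i + 1L, n))
      if (n - i + 1L <= link) y <- y + bridge + partner_mass
      masses <- c(masses, b, y)
    }
    masses
  }
  ma <- peptide_mono_mass(seq_a); mb <- peptide_mono_mass(seq_b)
  sort(c(one(seq_a, link_a, mb), one(seq_b, link_b, ma)))
}

# Maximum bipartite matching between theoretical ions and peaks by
# exhaustive recursion (feasible for <= 10 ions).
oracle_max_matching <- function(theoretical, peaks, frag_da, frag_ppm) {
  if (length(peaks) == 0L || length(theoretical) == 0L) return(0L)
  tol <- pmax(frag_da, theoretical * frag_ppm * 1e-6)
  compat <- outer(theoretical, peaks,
                  function(t, p) abs(t - p)) <= matrix(tol,
                                                       length(theoretical),
                                                       length(peaks))
  best <- 0L
  recurse <- function(i, used) {
    if (i > length(theoretical)) return(0L)
    top <- recurse(i + 1L, used)          # skip ion i
    for (j in which(compat[i, ])) {
      if (used[j]) next
      used[j] <- TRUE
      top <- max(top, 1L + recurse(i + 1L, used))
      used[j] <- FALSE
    }
    top
  }
  if (length(peaks) == 0L || length(theoretical) == 0L) return(0L)
  recurse(1L, rep(FALSE, length(peaks)))
}

# A toy two-chain PDB written as text; coordinates supplied per chain.
write_toy_pdb <- function(path, coords_a, coords_b,
                          resid_a = NULL, resid_b = NULL) {
  fmt <- function(serial, chain, resno, xyz, resid)
    sprintf("ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            serial, resid, chain, resno, xyz[1], xyz[2], xyz[3])
  if (is.null(resid_a)) resid_a <- rep("ALA", nrow(coords_a))
  if (is.null(resid_b)) resid_b <- rep("GLY", nrow(coords_b))
  ln <- c(
    vapply(seq_len(nrow(coords_a)), function(i)
      fmt(i, "A", i, coords_a[i, ], resid_a[i]), character(1L)),
    vapply(seq_len(nrow(coords_b)), function(i)
      fmt(nrow(coords_a) + i, "B", i, coords_b[i, ], resid_b[i]),
      character(1L)),
    "END")
  writeLines(ln, path)
  path
}

random_sequence <- function(n) {
  paste(sample(names(mass_constants()$residue), n, replace = TRUE),
        collapse = "")
}
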