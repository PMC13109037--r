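#' Three-criterion screening fractions per density
#'
#' For each density, the fraction of subject networks that are (i) connected
#' (> 80% of nodes in the largest component), (ii) modular (Q > 0.3), and
#' (iii) small-world (sigma > 1), plus the fraction passing all three.
#' Inequalities are strict.
#'
#' @param metrics data.frame with columns subject_id, density, lcc_fraction,
#'   modularity_Q, small_worldness (e.g. from [metrics_table()]).
#' @return data.frame, one row per density: density, frac_connected, frac_modular,
#'   frac_smallworld, frac_all.
#' @export
evaluate_criteria <- function(metrics) {
  need <- c("subject_id", "density", "lcc_fraction", "modularity_Q", "small_worldness")
  miss <- setdiff(need, names(metrics))
  if (length(miss)) abort("metrics table lacks column(s): %s", paste(miss, collapse = ", "))
  if (nrow(metrics) == 0) abort("empty metrics table")
  bad <- !stats::complete.cases(metrics[need])
  if (any(bad))
    abort("missing metric cells for: %s",
          paste(sprintf("%s@%.2f", metrics$subject_id[bad], metrics$density[bad]),
                collapse = ", "))
  ks <- sort(unique(metrics$density))
  n_subj <- length(unique(metrics$subject_id))
  rows <- lapply(ks, function(k) {
    mk <- metrics[metrics$density == k, ]
    if (nrow(mk) != n_subj)
      abort("density %.2f has %d rows, expected %d (one per subject)",
            k, nrow(mk), n_subj)
    conn <- mk$lcc_fraction > 0.8
    modu <- mk$modularity_Q > 0.3
    sw <- mk$small_worldness > 1
    data.frame(density = k,
               frac_connected = mean(conn), frac_modular = mean(modu),
               frac_smallworld = mean(sw), frac_all = mean(conn & modu & sw))
  })
  do.call(rbind, rows)
}

#' Select the analysis density from the screening table
#'
#' Retains the maximal contiguous run of grid densities at which the
#' pass-all fraction exceeds `majority` (ties between equally long runs go
#' to the lower-density run), and selects the mean of the retained grid
#' values, rounded half-away-from-zero to 2 decimals (the grid resolution).
#'
#' @param table criteria table from [evaluate_criteria()].
#' @param majority fraction of networks that must pass all three criteria
#'   (default 0.5, strict inequality).
#' @return list: `K_low`, `K_high`, `K_selected`, `retained` (densities in
#'   the run), `frac_all_at_selected` (pass-all fraction at the selected
#'   density, the published "over 85%"-style audit).
#' @export
select_density_range <- function(table, majority = 0.5) {
  stopifnot(is.data.frame(table), all(c("density", "frac_all") %in% names(table)))
  ord <- order(table$density)
  k <- table$density[ord]
  pass <- table$frac_all[ord] > majority
  if (!any(pass)) abort("no admissible density range: no density passes the majority rule")
  r <- rle(pass)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]  # which.max takes the first = lowest-density tie
  if (sum(r$lengths[runs] == max(r$lengths[runs])) > 1)
    message("multiple maximal passing runs; retaining the lowest-density run")
  idx <- starts[best]:ends[best]
  retained <- k[idx]
  k_sel <- round_half_away(mean(retained), 2)
  sel_row <- ord[idx][which.min(abs(retained - k_sel))]
  list(K_low = retained[1], K_high = retained[length(retained)],
       K_selected = k_sel, retained = retained,
       frac_all_at_selected = table$frac_all[sel_row])
}
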