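# Double-observer ground-truthing: concordance between the initial
# (near-real-time) and standard (2-60 day lag) visits to the same
# clusters, and the prey composition of the double-visited set.

#' Double-observer concordance summary
#'
#' A pair is discordant when the two observers disagree on the presence
#' of prey remains; the direction is attributed to whichever observer
#' recorded absence ("initial-missed" when visit 1 recorded absence,
#' "standard-missed" when visit 2 did). Composition classes over the
#' double-visited clusters: `large_prey` = remains found and the
#' large-size flag set (> 23.7 kg); `small_ungulate` = remains of a wild
#' ungulate not large-sized; `non_ungulate` = remains of a non-ungulate;
#' `none` = neither visit found remains. Remains "found" means found by
#' at least one observer.
#'
#' @param pairs observer-pair table, e.g. from
#'   `read_cluster_table(dialect = "double_observer")`: logical columns
#'   `visit1_feeding`, `visit2_feeding`, `large_prey`, `wild_ungulate`.
#' @return object of class `kc_concordance`: list with `n_pairs`,
#'   `n_discordant`, `discordance_rate`, `discordant_by_direction`
#'   (initial_missed, standard_missed), `composition` (proportions
#'   summing to 1), `discordant_by_size` (small_or_nonungulate, large).
#' @export
concordance_summary <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0) stop_kc("empty observer-pair table")
  v1 <- as.logical(pairs$visit1_feeding)
  v2 <- as.logical(pairs$visit2_feeding)
  large <- as.logical(pairs$large_prey)
  ung <- as.logical(pairs$wild_ungulate)
  n <- length(v1)
  disc <- v1 != v2
  found <- v1 | v2
  comp <- c(
    large_prey = sum(found & large),
    small_ungulate = sum(found & !large & ung),
    non_ungulate = sum(found & !ung),
    none = sum(!found)
  ) / n
  structure(
    list(
      n_pairs = n,
      n_discordant = sum(disc),
      discordance_rate = sum(disc) / n,
      discordant_by_direction = c(
        initial_missed = sum(disc & !v1),
        standard_missed = sum(disc & !v2)
      ),
      composition = comp,
      discordant_by_size = c(
        small_or_nonungulate = sum(disc & !(large & found)),
        large = sum(disc & large & found)
      )
    ),
    class = "kc_concordance"
  )
}

#' @export
print.kc_concordance <- function(x, ...) {
  cat(sprintf(
    "<kc_concordance> %d pairs, %d discordant (%.1f%%): %d initial-missed, %d standard-missed\n",
    x$n_pairs, x$n_discordant, 100 * x$discordance_rate,
    x$discordant_by_direction["initial_missed"],
    x$discordant_by_direction["standard_missed"]
  ))
  cat("  composition:",
      paste(sprintf("%s %.1f%%", names(x$composition),
                    100 * x$composition), collapse = ", "), "\n")
  invisible(x)
}
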