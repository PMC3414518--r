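#' Group-level option counts for the tradition (option-bias) test
#'
#' @param group_id group labels.
#' @param n_flap,n_tube counts of units (individuals or manipulations)
#'   using each option-type per group.
#' @param seeded_option option the group's demonstrator was trained on
#'   (`"flap"`, `"tube"`, or `"none"` for control groups).
#' @return data.frame of class `smfm_option_counts`.
#' @export
option_count_table <- function(group_id, n_flap, n_tube,
                               seeded_option = "none") {
  stopifnot(length(n_flap) == length(group_id),
            length(n_tube) == length(group_id))
  if (any(n_flap < 0 | n_tube < 0)) stop("counts must be >= 0", call. = FALSE)
  out <- data.frame(group_id = as.character(group_id),
                    n_flap = as.numeric(n_flap),
                    n_tube = as.numeric(n_tube),
                    seeded_option = rep_len(as.character(seeded_option),
                                            length(group_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("smfm_option_counts", "data.frame")
  out
}

#' Tabulate option use per group from an event log
#'
#' @param log a validated [event_log()].
#' @param unit `"individuals"` (count each non-demonstrator once, by the
#'   option-type it used most; individuals using neither are dropped) or
#'   `"manipulations"` (count every non-demonstrator bout).
#' @return an [option_count_table()].
#' @export
count_option_use <- function(log, unit = c("individuals", "manipulations")) {
  unit <- match.arg(unit)
  ind <- log$individuals
  bt <- log$bouts[log$bouts$option_type %in% OPTION_TYPES, , drop = FALSE]
  bt <- bt[!ind$is_demonstrator[match(bt$individual_id, ind$id)], ,
           drop = FALSE]
  groups <- sort(unique(ind$group_id))
  bt$group_id <- ind$group_id[match(bt$individual_id, ind$id)]
  nf <- nt <- numeric(length(groups))
  for (gi in seq_along(groups)) {
    b <- bt[bt$group_id == groups[gi], ]
    if (unit == "manipulations") {
      nf[gi] <- sum(b$option_type == "flap")
      nt[gi] <- sum(b$option_type == "tube")
    } else {
      for (id in unique(b$individual_id)) {
        cnt <- table(factor(b$option_type[b$individual_id == id],
                            levels = OPTION_TYPES))
        if (cnt["flap"] >= cnt["tube"]) nf[gi] <- nf[gi] + 1
        else nt[gi] <- nt[gi] + 1
      }
    }
  }
  seeded <- vapply(groups, function(g) {
    d <- ind[ind$group_id == g & ind$is_demonstrator, ]
    if (nrow(d)) d$trained_option_type[1] else "none"
  }, "")
  option_count_table(groups, nf, nt, seeded)
}

#' Randomization test for group-level option biases (traditions)
#'
#' Tests whether groups are disproportionately biased towards one
#' option-type, the signature of behavioural traditions.  The statistic
#' is the group-size-weighted sum of absolute deviations of each group's
#' flap proportion from the pooled proportion,
#' `sum_g n_g * |p_g - p_pooled|`.  The null distribution reallocates
#' every unit's option independently with probability equal to the pooled
#' proportion (group sizes preserved), and the p-value uses the add-one
#' Monte-Carlo correction `p = (1 + #{perm >= obs}) / (1 + n_perm)`.
#'
#' @param table an [option_count_table()].
#' @param unit label recorded in the output (`"individuals"` or
#'   `"manipulations"`); the table must already hold counts at that unit.
#' @param n_perm number of permutations (`>= 999`).
#' @param seed integer seed for reproducibility.
#' @param seeded_only if `TRUE`, drop groups with `seeded_option ==
#'   "none"` before testing.
#' @return object of class `smfm_option_bias`: list with `statistic`,
#'   `p_value`, `n_perm`, `unit`, `pooled_proportion`.
#' @export
option_bias_test <- function(table, unit = c("individuals", "manipulations"),
                             n_perm = 9999, seed = NULL,
                             seeded_only = FALSE) {
  unit <- match.arg(unit)
  if (n_perm < 999) stop("n_perm must be >= 999", call. = FALSE)
  if (seeded_only) table <- table[table$seeded_option != "none", , drop = FALSE]
  if (nrow(table) < 2) stop("need at least 2 groups", call. = FALSE)
  n_g <- table$n_flap + table$n_tube
  if (any(n_g == 0)) stop("empty group in the option table", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  stat_fun <- function(flap) {
    p_g <- flap / n_g
    p_pool <- sum(flap) / sum(n_g)
    sum(n_g * abs(p_g - p_pool))
  }
  obs <- stat_fun(table$n_flap)
  p_pool <- sum(table$n_flap) / sum(n_g)
  # vectorized null: each unit's option is a coin flip at the pooled rate
  perm_flap <- matrix(rbinom(n_perm * length(n_g), rep(n_g, n_perm),
                             p_pool), nrow = length(n_g))
  perm_tot <- colSums(perm_flap)
  perm_pool <- perm_tot / sum(n_g)
  perm_stat <- colSums(abs(perm_flap / n_g -
                             rep(perm_pool, each = length(n_g))) * n_g)
  p <- (1 + sum(perm_stat >= obs - 1e-12)) / (1 + n_perm)
  structure(list(statistic = obs, p_value = p, n_perm = n_perm,
                 unit = unit, pooled_proportion = p_pool,
                 n_groups = nrow(table)),
            class = "smfm_option_bias")
}

#' @export
print.smfm_option_bias <- function(x, ...) {
  cat(sprintf(
    "<smfm_option_bias> statistic = %.3f, P = %.4g (%d groups, %s, %d permutations)\n",
    x$statistic, x$p_value, x$n_groups, x$unit, x$n_perm))
  invisible(x)
}
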