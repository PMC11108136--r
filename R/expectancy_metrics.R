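# Life and health expectancies from trajectory samples, via the
# standard demographic person-years formula
#   e_{x,j} = sum_{y >= x} L_{y,j} / l_x ,
# with l_x the survivors at exact age x and L_{y,j} the person-years
# lived at age y in state j.

# Shared assembly of an expectancy table from person-years L[age, state]
# and survivors lx[age] (counts or probability mass). Ages with lx == 0
# are dropped (table truncated).
expectancy_rows <- function(sex, L, lx) {
  keep <- lx > 0
  last <- max(which(keep))
  L <- L[seq_len(last), , drop = FALSE]
  lx <- lx[seq_len(last)]
  # remaining person-years from age x: reverse cumulative sums
  R <- apply(L, 2, function(col) rev(cumsum(rev(col))))
  R <- matrix(R, ncol = 6L)
  e_state <- R / lx
  df <- data.frame(sex = sex, age = seq_len(last) - 1L, lx = lx,
                   ex = rowSums(e_state), stringsAsFactors = FALSE)
  colnames(e_state) <- paste0("ex_s", 1:6)
  cbind(df, e_state)
}

as_expectancy_table <- function(df, convention, kind, censored = 0L) {
  structure(df, class = c("expectancy_table", "data.frame"),
            convention = convention, kind = kind, censored = censored)
}

#' Expectancies from a trajectory sample
#'
#' Computes, per sex and integer age x: survivors `l_x` (trajectories
#' with years lived > x), total remaining life expectancy `e_x`, and
#' state-specific expectancies `e_{x,j}` for the six health states. The
#' healthy life expectancy series (HLE) is the state-1 column `ex_s1`.
#' Censored trajectories contribute person-years up to censoring only;
#' their number is recorded in the `"censored"` attribute.
#'
#' @param sample A [simulate_trajectories()] result.
#' @return An `expectancy_table`: data.frame with columns `sex`, `age`,
#'   `lx`, `ex`, `ex_s1`..`ex_s6`, satisfying
#'   `ex == ex_s1 + ... + ex_s6` at every row.
#' @export
expectancies_from_sample <- function(sample) {
  stopifnot(inherits(sample, "trajectory_sample"))
  present <- SEXES[SEXES %in% sample$sex]
  if (!length(present)) stop_validation("empty trajectory sample")
  tabs <- lapply(present, function(sex) {
    st <- sample$states[sample$sex == sex, , drop = FALSE]
    n_ages <- ncol(st)
    L <- matrix(0, n_ages, 6L)
    for (j in 1:6) L[, j] <- colSums(!is.na(st) & st == j)
    lx <- rowSums(L)  # alive at exact age x == occupying some live state
    expectancy_rows(sex, L, lx)
  })
  as_expectancy_table(do.call(rbind, tabs), convention = "whole_year",
                      kind = "monte_carlo", censored = sum(sample$censored))
}

#' Monte Carlo standard errors of expectancies
#'
#' Standard errors of `e_{x,j}` (and total `e_x`) estimated from the
#' between-trajectory variance of remaining person-years in state j
#' from age x, among trajectories alive at x: `sd / sqrt(l_x)`.
#'
#' @param sample A `trajectory_sample`.
#' @return Data.frame with columns `sex`, `age`, `se_ex`,
#'   `se_ex_s1`..`se_ex_s6`, aligned with [expectancies_from_sample()].
#' @export
expectancy_standard_errors <- function(sample) {
  stopifnot(inherits(sample, "trajectory_sample"))
  out <- lapply(SEXES[SEXES %in% sample$sex], function(sex) {
    st <- sample$states[sample$sex == sex, , drop = FALSE]
    n_ages <- ncol(st)
    alive <- !is.na(st)
    years <- rowSums(alive)
    # remaining[j]: n x n_ages matrix of years in state j from age x on
    se <- matrix(NA_real_, n_ages, 7L)
    rem_total <- matrix(0, nrow(st), n_ages)
    rem_j <- vector("list", 6L)
    for (j in 1:6) {
      R <- (alive & st == j) * 1
      for (x in (n_ages - 1L):1L) R[, x] <- R[, x] + R[, x + 1L]
      rem_j[[j]] <- R
      rem_total <- rem_total + R
    }
    for (x in seq_len(n_ages)) {
      at_risk <- years > (x - 1L)
      lx <- sum(at_risk)
      if (lx == 0L) break
      se[x, 7L] <- stats::sd(rem_total[at_risk, x]) / sqrt(lx)
      for (j in 1:6) se[x, j] <- stats::sd(rem_j[[j]][at_risk, x]) / sqrt(lx)
    }
    keep <- !is.na(se[, 7L])
    df <- data.frame(sex = sex, age = which(keep) - 1L,
                     se_ex = se[keep, 7L], stringsAsFactors = FALSE)
    sej <- se[keep, 1:6, drop = FALSE]
    colnames(sej) <- paste0("se_ex_s", 1:6)
    cbind(df, sej)
  })
  do.call(rbind, out)
}

#' Report expectancies at ages of interest
#'
#' Extracts `e_x` and `e_{x,j}` at the requested ages (defaults: birth
#' and 65) per sex, writes them as CSV if asked, and optionally draws a
#' stacked-area figure of the state-specific expectancy series across
#' all ages (requires ggplot2).
#'
#' @param table An `expectancy_table`.
#' @param ages Ages of interest; ages beyond the table are omitted with
#'   a warning. Use `seq(0, 90, 10)` for a decadal summary.
#' @param file Optional CSV output path.
#' @param figure Optional figure output path (format by extension, e.g.
#'   `.png`/`.svg`).
#' @return Data.frame with one row per (sex, requested age): `sex`,
#'   `age`, `ex`, `ex_s1`..`ex_s6`, `hle` (alias of `ex_s1`).
#' @export
expectancy_report <- function(table, ages = c(0, 65), file = NULL, figure = NULL) {
  stopifnot(inherits(table, "expectancy_table"))
  missing_ages <- setdiff(ages, table$age)
  if (length(missing_ages)) {
    warning("age(s) beyond the table omitted: ", paste(missing_ages, collapse = ", "))
    ages <- setdiff(ages, missing_ages)
  }
  rep_df <- table[table$age %in% ages,
                  c("sex", "age", "ex", paste0("ex_s", 1:6)), drop = FALSE]
  rep_df$hle <- rep_df$ex_s1
  rownames(rep_df) <- NULL
  if (!is.null(file)) {
    utils::write.csv(rep_df, file, row.names = FALSE)
  }
  if (!is.null(figure)) {
    if (!requireNamespace("ggplot2", quietly = TRUE)) {
      warning("ggplot2 not available; figure skipped")
    } else {
      long <- do.call(rbind, lapply(1:6, function(j) {
        data.frame(sex = table$sex, age = table$age,
                   state = factor(health_state_labels()[j],
                                  levels = rev(health_state_labels()[1:6])),
                   years = table[[paste0("ex_s", j)]])
      }))
      p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$age, y = .data$years,
                                              fill = .data$state)) +
        ggplot2::geom_area() +
        ggplot2::facet_wrap(~sex) +
        ggplot2::labs(x = "Age (years)", y = "Remaining expectancy (years)",
                      fill = "Health state") +
        ggplot2::theme_minimal()
      ggplot2::ggsave(figure, p, width = 10, height = 5)
    }
  }
  rep_df
}

# ---- trajectory file format ------------------------------------------------

#' Write a trajectory sample to delimited text
#'
#' One row per person: sex, age at death (empty when censored),
#' censoring flag, and the state sequence run-length encoded as
#' `state:length` segments joined by `;` (e.g. `1:60;3:21`).
#'
#' @param sample A `trajectory_sample`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(sample, path) {
  enc <- apply(sample$states, 1, function(r) {
    r <- r[!is.na(r)]
    z <- rle(r)
    paste(sprintf("%d:%d", z$values, z$lengths), collapse = ";")
  })
  df <- data.frame(sex = sample$sex, age_at_death = sample$age_at_death,
                   censored = sample$censored, states = enc,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a trajectory sample written by [write_trajectories()]
#'
#' @param path Input path.
#' @param seed,max_attained_age Metadata to attach (the file itself
#'   carries states only); `max_attained_age` defaults to the longest
#'   sequence present.
#' @return A `trajectory_sample`.
#' @export
read_trajectories <- function(path, seed = NA_integer_, max_attained_age = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  seqs <- lapply(strsplit(df$states, ";", fixed = TRUE), function(segs) {
    parts <- do.call(rbind, strsplit(segs, ":", fixed = TRUE))
    rep(as.integer(parts[, 1]), as.integer(parts[, 2]))
  })
  n_ages <- max(lengths(seqs))
  if (is.null(max_attained_age)) max_attained_age <- n_ages - 1L
  st <- matrix(NA_integer_, length(seqs), max_attained_age + 1L)
  for (r in seq_along(seqs)) st[r, seq_along(seqs[[r]])] <- seqs[[r]]
  structure(
    list(sex = df$sex, states = st,
         age_at_death = as.integer(df$age_at_death),
         censored = as.logical(df$censored),
         seed = as.integer(seed),
         max_attained_age = as.integer(max_attained_age),
         n_per_sex = as.integer(sum(df$sex == "female"))),
    class = "trajectory_sample")
}
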