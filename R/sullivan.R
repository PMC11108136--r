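# Classical period life table, the Sullivan healthy life expectancy
# estimator (prevalence x life-table person-years), and the comparison
# of Sullivan against multistate estimates. Includes a consistency
# check: under stationarity and matched person-year conventions the two
# estimators coincide.

#' Convert central death rates to annual death probabilities
#'
#' `q_x = m_x / (1 + (1 - a_x) m_x)` under the linear person-years
#' assumption.
#'
#' @param mx Central death rates.
#' @param ax Separation factor (fraction of the year lived by those
#'   dying in the interval), default 0.5.
#' @return Annual death probabilities.
#' @export
mx_to_qx <- function(mx, ax = 0.5) {
  mx / (1 + (1 - ax) * mx)
}

#' Build a period life table
#'
#' Standard single-year period life table from annual death
#' probabilities: `l_{x+1} = l_x (1 - q_x)`,
#' `L_x = l_{x+1} + a_x (l_x - l_{x+1})`, `T_x = sum_{y >= x} L_y`,
#' `e_x = T_x / l_x`. The last age may be an open terminal group closed
#' with a central death rate: `L_term = l_term / m_term`. Without a
#' terminal rate, the last `q_x` must equal 1 so the table closes.
#'
#' @param qx Annual death probabilities for the closed ages, all in
#'   \[0,1\].
#' @param ages Integer ages the probabilities refer to (default
#'   `0..length(qx)-1`).
#' @param ax Separation factor(s), recycled over closed ages. 0.5 is the
#'   standard demographic convention; use 1 to match whole-year cycle
#'   accounting.
#' @param radix Starting cohort size (expectancies are invariant to it).
#' @param terminal_mx Central death rate of the open group following the
#'   last closed age, or `NULL` when `qx` already closes the table.
#' @return Data.frame with columns `age`, `qx`, `ax`, `lx`, `dx`, `Lx`,
#'   `Tx`, `ex`; class `life_table`.
#' @export
build_life_table <- function(qx, ages = seq_along(qx) - 1L, ax = 0.5,
                             radix = 100000, terminal_mx = NULL) {
  if (any(qx < 0 | qx > 1)) stop_validation("'qx' must lie in [0,1]")
  K <- length(qx)
  ax <- rep_len(ax, K)
  l <- radix * cumprod(c(1, 1 - qx))
  d <- l[1:K] - l[2:(K + 1)]
  L <- l[2:(K + 1)] + ax * d
  if (!is.null(terminal_mx)) {
    if (terminal_mx <= 0) {
      stop_validation("zero terminal mortality: the open age group cannot close")
    }
    l <- c(l[1:K], l[K + 1])
    L <- c(L, l[K + 1] / terminal_mx)
    d <- c(d, l[K + 1])
    ages <- c(ages, ages[K] + 1L)
    qx <- c(qx, 1)
    ax <- c(ax, NA_real_)
  } else {
    if (qx[K] != 1) {
      stop_validation("last qx must be 1 when no terminal rate is given (open group must close)")
    }
    l <- l[1:K]
  }
  Tx <- rev(cumsum(rev(L)))
  ex <- ifelse(l > 0, Tx / l, NA_real_)
  structure(data.frame(age = ages, qx = qx, ax = ax, lx = l, dx = d,
                       Lx = L, Tx = Tx, ex = ex),
            class = c("life_table", "data.frame"), radix = radix)
}

#' Sullivan healthy life expectancy
#'
#' `HLE_x = sum_{y >= x} pi_y L_y / l_x`: life-table person-years
#' weighted by the cross-sectional prevalence of good health.
#'
#' @param life_table A [build_life_table()] result.
#' @param pi_x Prevalence of the healthy state per table age, in
#'   \[0,1\].
#' @return Data.frame with columns `age`, `hle`.
#' @export
sullivan_hle <- function(life_table, pi_x) {
  stopifnot(inherits(life_table, "life_table"))
  if (length(pi_x) != nrow(life_table)) {
    stop_validation("'pi_x' must supply one prevalence per life-table age")
  }
  if (any(pi_x < 0 | pi_x > 1)) stop_validation("'pi_x' must lie in [0,1]")
  healthy_T <- rev(cumsum(rev(pi_x * life_table$Lx)))
  data.frame(age = life_table$age,
             hle = ifelse(life_table$lx > 0, healthy_T / life_table$lx, NA_real_))
}

#' Standard errors of Sullivan HLE
#'
#' Conventional binomial variance propagation of the prevalence:
#' `Var(HLE_x) = l_x^{-2} sum_{y >= x} L_y^2 pi_y (1 - pi_y) / n_y`,
#' ignoring mortality sampling error and survey design effects.
#'
#' @inheritParams sullivan_hle
#' @param n_x Prevalence sample size per age.
#' @return Data.frame with columns `age`, `se`.
#' @export
sullivan_hle_se <- function(life_table, pi_x, n_x) {
  stopifnot(inherits(life_table, "life_table"))
  v <- life_table$Lx^2 * pi_x * (1 - pi_x) / n_x
  data.frame(age = life_table$age,
             se = sqrt(rev(cumsum(rev(v)))) / life_table$lx)
}

#' Compare multistate and Sullivan healthy life expectancies
#'
#' @param hle_mms Multistate HLE values (years).
#' @param hle_sullivan Sullivan HLE values (years), aligned with
#'   `hle_mms`.
#' @param age,sex Optional labels, recycled.
#' @return Data.frame with columns `age`, `sex`, `hle_mms`,
#'   `hle_sullivan`, `difference` (= Sullivan - MMS, exactly).
#' @export
#' @examples
#' compare_hle(2.43, 10.68, age = 65, sex = "female")$difference
compare_hle <- function(hle_mms, hle_sullivan, age = NA_integer_, sex = NA_character_) {
  if (length(hle_mms) != length(hle_sullivan)) {
    stop_validation("'hle_mms' and 'hle_sullivan' must have equal length")
  }
  data.frame(age = rep_len(age, length(hle_mms)),
             sex = rep_len(sex, length(hle_mms)),
             hle_mms = hle_mms, hle_sullivan = hle_sullivan,
             difference = hle_sullivan - hle_mms,
             stringsAsFactors = FALSE)
}

#' Sullivan-multistate consistency check
#'
#' Under stationary transition probabilities, the Sullivan estimator
#' applied to the chain's own mortality and cross-sectional healthy
#' prevalence must reproduce the multistate healthy expectancy exactly,
#' provided the person-year conventions match. This check derives
#' `q_x = 1 - l_{x+1}/l_x` and `pi_x` (healthy share among those alive
#' at x) from the analytic state occupancy of the chain, builds a life
#' table with `a_x = 1` (whole-year credit, matching the simulation
#' engine) closed at the censoring age, and compares the resulting
#' Sullivan HLE with the analytic multistate healthy expectancy age by
#' age.
#'
#' @inheritParams analytic_expectancies
#' @return Data.frame with columns `sex`, `age`, `hle_sullivan`,
#'   `hle_multistate`, `difference`; attribute `"max_abs_diff"`.
#' @export
sullivan_consistency_check <- function(yearly, init, max_attained_age = 110L) {
  out <- lapply(SEXES, function(sex) {
    occ <- state_occupancy(yearly, init[sex, ], sex, max_attained_age)
    lx <- occ$lx
    last <- max(which(lx > 0))
    lx <- lx[seq_len(last)]
    pi_x <- occ$L[seq_len(last), 1] / lx
    qx <- c(1 - lx[-1] / lx[-last], 1)  # close at the censoring age
    qx <- pmin(pmax(qx, 0), 1)          # guard occupancy round-off
    lt <- build_life_table(qx, ages = seq_len(last) - 1L, ax = 1, radix = 1)
    hle_s <- sullivan_hle(lt, pi_x)
    an <- analytic_expectancies(yearly, init, max_attained_age)
    an <- an[an$sex == sex, ]
    data.frame(sex = sex, age = hle_s$age, hle_sullivan = hle_s$hle,
               hle_multistate = an$ex_s1[match(hle_s$age, an$age)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$difference <- out$hle_sullivan - out$hle_multistate
  structure(out, max_abs_diff = max(abs(out$difference)))
}

# ---- packaged reference values --------------------------------------------

#' Published Sullivan HLE reference values, Catalonia 2017
#'
#' Official Sullivan-method healthy life expectancy estimates (with
#' standard errors) by sex at selected ages, from the Catalan health
#' department's 2017 reporting (mortality register plus
#' self-perceived-health survey prevalence). Used as the comparison
#' reference for multistate estimates; not re-derived by this package.
#'
#' @return Data.frame with columns `age`, `hle_female`, `se_female`,
#'   `hle_male`, `se_male`.
#' @export
reference_hle_sullivan <- function() {
  utils::read.csv(system.file("extdata", "hle_sullivan_catalonia_2017.csv",
                              package = "hlemms"))
}

#' Published life expectancy reference values, 2017
#'
#' Life expectancy at decadal ages by sex: the multistate
#' microsimulation estimates published for the Baix Empordà population
#' (2016-2017 registry) alongside the official Catalan and Spanish
#' period life-table values for 2017.
#'
#' @return Data.frame with columns `age`, `mms_female`, `mms_male`,
#'   `mms_total`, `catalonia_female`, `catalonia_male`,
#'   `catalonia_total`, `spain_female`, `spain_male`, `spain_total`.
#' @export
reference_life_expectancy <- function() {
  utils::read.csv(system.file("extdata", "le_reference_2017.csv",
                              package = "hlemms"))
}

#' Published multistate HLE/LE point estimates, Baix Empordà 2016-2017
#'
#' Headline healthy life expectancy and total life expectancy point
#' estimates at birth and age 65 from the published multistate
#' microsimulation study of the Baix Empordà population.
#'
#' @return Data.frame with columns `age`, `sex`, `hle_mms`, `le_mms`.
#' @export
reference_hle_mms <- function() {
  utils::read.csv(system.file("extdata", "reference_hle_mms_2017.csv",
                              package = "hlemms"))
}
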