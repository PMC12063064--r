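# Independent oracles used to cross-check the package implementations.

# Maximum number of clusterable metastases over all contiguous partitions of
# the sorted diameters, subject to the linkage rule. Exhaustive: 2^(n-1)
# cut patterns. Blocks of size 1 are isolated; blocks of size >= 2 must
# satisfy the rule to be a valid wave.
brute_force_sigma_c <- function(diameters, tolerance, linkage = "single") {
  d <- sort(diameters)
  n <- length(d)
  if (n == 1L) return(0L)
  block_ok <- function(b) {
    if (linkage == "single") all(diff(b) <= tolerance)
    else max(b) - min(b) <= tolerance
  }
  best <- 0L
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0L, cuts, n)
    sigma_c <- 0L
    valid <- TRUE
    for (k in seq_len(length(bounds) - 1L)) {
      b <- d[(bounds[k] + 1L):bounds[k + 1L]]
      if (length(b) >= 2L) {
        if (!block_ok(b)) { valid <- FALSE; break }
        sigma_c <- sigma_c + length(b)
      }
    }
    if (valid && sigma_c > best) best <- sigma_c
  }
  best
}

# Gehan's generalized Wilcoxon via pairwise definite-ordering scores with
# the permutation variance; independent of the at-risk-weighted log-rank
# formulation used in the package.
gehan_u_oracle <- function(time_a, event_a, time_b, event_b) {
  t <- c(time_a, time_b); e <- c(event_a, event_b)
  in_a <- c(rep(TRUE, length(time_a)), rep(FALSE, length(time_b)))
  n_tot <- length(t)
  s <- numeric(n_tot)
  for (i in seq_len(n_tot)) {
    for (j in seq_len(n_tot)) {
      if (i == j) next
      longer <- (t[i] > t[j] && e[j] == 1) ||
        (t[i] == t[j] && e[j] == 1 && e[i] == 0)
      shorter <- (t[j] > t[i] && e[i] == 1) ||
        (t[j] == t[i] && e[i] == 1 && e[j] == 0)
      s[i] <- s[i] + longer - shorter
    }
  }
  w <- sum(s[in_a])
  m <- sum(in_a); k <- n_tot - m
  v <- m * k / (n_tot * (n_tot - 1)) * sum(s^2)
  list(w = w, variance = v, chisq = w^2 / v,
       p = stats::pchisq(w^2 / v, 1, lower.tail = FALSE))
}

# numerator of the at-risk-weighted log-rank statistic, for the exact
# identity check against the pairwise-score sum
gehan_numerator <- function(time_a, event_a, time_b, event_b) {
  t <- c(time_a, time_b); e <- c(event_a, event_b)
  in_a <- c(rep(TRUE, length(time_a)), rep(FALSE, length(time_b)))
  s <- 0
  for (tt in sort(unique(t[e == 1]))) {
    at <- t >= tt
    n_j <- sum(at); n1_j <- sum(at & in_a)
    d_j <- sum(e == 1 & t == tt); d1_j <- sum(e == 1 & t == tt & in_a)
    s <- s + n_j * (d1_j - d_j * n1_j / n_j)
  }
  s
}

# minimal valid patients table for survival fixtures
make_patients <- function(n, time_from_mets, event, timing = "synchronous",
                          lead = 0) {
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    sex = "female", primary_location = "head",
    timing = timing,
    months_primary_to_mets = lead,
    followup_from_primary_months = lead + time_from_mets,
    followup_from_mets_months = time_from_mets,
    event = ifelse(event == 1, "died", "censored"),
    stringsAsFactors = FALSE
  )
}

write_cohort_fixture <- function(dir, metastases, patients) {
  mf <- file.path(dir, "metastases.csv")
  pf <- file.path(dir, "patients.csv")
  utils::write.csv(metastases, mf, row.names = FALSE, quote = FALSE)
  utils::write.csv(patients, pf, row.names = FALSE, quote = FALSE)
  list(metastases = mf, patients = pf)
}

toy_patients <- function(ids, timing = "synchronous") {
  data.frame(
    patient_id = ids, sex = "male", primary_location = "head",
    timing = timing,
    months_primary_to_mets = ifelse(timing == "synchronous", 0, 5),
    followup_from_primary_months = 12,
    event = "died", stringsAsFactors = FALSE
  )
}
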