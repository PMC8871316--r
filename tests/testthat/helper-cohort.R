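# Shared fixtures and independent oracles for the test suite.

# expand a contingency table into the per-item pair list it tallies
expand_pairs <- function(tab) {
  labels <- rownames(tab)
  idx <- which(unclass(tab) > 0, arr.ind = TRUE)
  n <- unclass(tab)[idx]
  data.frame(
    a = rep(labels[idx[, 1]], n),
    b = rep(labels[idx[, 2]], n),
    stringsAsFactors = FALSE
  )
}

# brute-force weighted kappa over the raw item list: P_o averages the
# weight of each observed pair; P_e averages the weight over all N^2
# rater-A x rater-B item combinations. Independent of the table path.
kappa_brute <- function(a, b, labels, scheme) {
  k <- length(labels)
  d <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  w <- switch(scheme,
              unweighted = (d == 0) * 1,
              linear = 1 - d,
              quadratic = 1 - d^2)
  ia <- match(a, labels)
  ib <- match(b, labels)
  po <- mean(w[cbind(ia, ib)])
  pe <- mean(w[as.matrix(expand.grid(ia, ib))])
  (po - pe) / (1 - pe)
}

# hand-built two-screenee cohort with known categories:
#   s1/n1: MV 50 (neg), diameter 6.5 -> EV 143.8 (ind); follow-up doubles
#   s1/n2: MV 300 (pos), diameter 9  -> EV 381.7 (pos); no follow-up
#   s2/n1: MV 120 (ind), diameter 8  -> EV 268.1 (pos); follow-up halves
tiny_cohort <- function() {
  tibble::tibble(
    screenee_id = c("s1", "s1", "s2", "s1", "s2"),
    nodule_id = c("n1", "n2", "n1", "n1", "n1"),
    timepoint = c(0L, 0L, 0L, 1L, 1L),
    days_from_baseline = c(0L, 0L, 0L, 365L, 365L),
    max_diameter_mm = c(6.5, 9, 8, 6.5 * 2^(1 / 3), 8 / 2^(1 / 3)),
    measured_volume_mm3 = c(50, 300, 120, 100, 60)
  )
}

# build a per-nodule cohort whose PN-based analysis reproduces the two
# given fixture blocks exactly: representative volumes per outcome
# category, and follow-up volumes/diameters tuned to hit target VDTs.
cohort_from_fixture <- function(ldct_tab, vdt_tab) {
  mv_rep <- c(negative = 50, indeterminate = 150, positive = 300)
  # diameters whose sphere volume lands in each category
  d_rep <- c(negative = 4.5, indeterminate = 6.5, positive = 8.5)
  vdt_rep <- c(probably_malignant = 300, indeterminate = 500,
               probably_benign = 700)

  ldct_pairs <- expand_pairs(ldct_tab)
  vdt_pairs <- expand_pairs(vdt_tab)
  n_ldct <- nrow(ldct_pairs)
  n_vdt <- nrow(vdt_pairs)
  stopifnot(n_vdt <= n_ldct)

  base <- tibble::tibble(
    screenee_id = sprintf("s%04d", seq_len(n_ldct)),
    nodule_id = "n1",
    timepoint = 0L,
    days_from_baseline = 0L,
    max_diameter_mm = unname(d_rep[ldct_pairs$b]),
    measured_volume_mm3 = unname(mv_rep[ldct_pairs$a])
  )
  # first n_vdt nodules get a follow-up realising the target VDT pair
  mv_target <- unname(vdt_rep[vdt_pairs$a])
  ev_target <- unname(vdt_rep[vdt_pairs$b])
  dt <- 365
  v1 <- base$measured_volume_mm3[seq_len(n_vdt)]
  d1 <- base$max_diameter_mm[seq_len(n_vdt)]
  v2 <- v1 * 2^(dt / mv_target)
  d2 <- d1 * 2^(dt / (3 * ev_target))  # volume ratio 2^(dt/vdt) = (d2/d1)^3
  fu <- tibble::tibble(
    screenee_id = base$screenee_id[seq_len(n_vdt)],
    nodule_id = "n1",
    timepoint = 1L,
    days_from_baseline = as.integer(dt),
    max_diameter_mm = d2,
    measured_volume_mm3 = v2
  )
  dplyr::bind_rows(base, fu)
}
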