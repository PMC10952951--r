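# Shared fixtures: small phantoms and cohort tables built in code.

tinyPhantom <- function(noiseSigma = 0, gridShape = c(16, 16, 16),
                        seed = 11L, ...) {
  makePhantom(phantomSpec(gridShape = gridShape, noiseSigma = noiseSigma,
                          ...), seed = seed)
}

# minimal valid cohort row(s)
cohortRow <- function(subject_id = "s1", group = "preterm", ga_mri = 24,
                      ga_delivery = 26, maternal_age = 30, bmi = 24,
                      ethnicity = "White", parity = 0, liveborn = 1,
                      live_to_discharge = 1, rds = 0, ivh_grade34 = 0,
                      bpd = 0, nec = 0, histology_available = 0,
                      chorioamnionitis = 0, funisitis = 0) {
  data.frame(subject_id = subject_id, group = group, ga_mri = ga_mri,
             ga_delivery = ga_delivery, maternal_age = maternal_age,
             bmi = bmi, ethnicity = ethnicity, parity = parity,
             liveborn = liveborn, live_to_discharge = live_to_discharge,
             rds = rds, ivh_grade34 = ivh_grade34, bpd = bpd, nec = nec,
             histology_available = histology_available,
             chorioamnionitis = chorioamnionitis, funisitis = funisitis)
}

fixturePath <- function() {
  system.file("extdata", "preterm_outcomes.csv", package = "fetalT2star")
}

# brute-force 6-connected erosion: the independent oracle for erodeMask
bruteErode <- function(g) {
  d <- dim(g)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!g[i, j, k]) next
    keep <- i > 1 && i < d[1] && j > 1 && j < d[2] && k > 1 && k < d[3]
    if (keep)
      keep <- g[i - 1, j, k] && g[i + 1, j, k] && g[i, j - 1, k] &&
        g[i, j + 1, k] && g[i, j, k - 1] && g[i, j, k + 1]
    out[i, j, k] <- keep
  }
  out
}
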