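# shared fixtures, built in code

# a plausible healthy 5-point record in clinical units
make_clinical_record <- function(subject_id = "s1",
                                 g = c(86.4, 120, 135, 110, 95),
                                 i = c(4.32, 25, 40, 30, 15)) {
  ogtt_record(subject_id, c(0, 30, 60, 90, 120), g, i,
              glycemia_unit = "mg/dL", insulinemia_unit = "uU/mL")
}

# noiseless record simulated from known parameters
make_truth_record <- function(params = model_parameters(), id = "truth") {
  simulation_to_record(simulate_ogtt(params), subject_id = id)
}

# brute-force Youden search: plain double loop, independent of the
# vectorised implementation
brute_force_youden <- function(xh, xnh) {
  pooled <- sort(unique(c(xh, xnh)))
  cuts <- c(pooled[1] - 1,
            if (length(pooled) > 1)
              (pooled[-1] + pooled[-length(pooled)]) / 2,
            pooled[length(pooled)] + 1)
  best_J <- -Inf
  for (cut in cuts) {
    for (dir in c("above", "below")) {
      if (dir == "above") {
        J <- mean(xnh > cut) + mean(xh <= cut) - 1
      } else {
        J <- mean(xnh < cut) + mean(xh >= cut) - 1
      }
      if (J > best_J) best_J <- J
    }
  }
  best_J
}

# all set partitions of 1..n (Bell-number enumeration, fine for n <= 8)
all_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  smaller <- all_partitions(n - 1)
  out <- list()
  for (p in smaller) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(q[[k]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}
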