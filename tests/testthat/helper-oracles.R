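# Independent oracles and small random-instance generators.
#
# The RED oracle below deliberately re-derives the forward model with plain
# nested loops and scalar arithmetic, so that screen_solvents() is checked
# against an implementation that shares no code with it.

oracle_red_matrix <- function(solutes, solvents) {
  m <- matrix(NA_real_, nrow(solutes), nrow(solvents),
              dimnames = list(solutes$name, solvents$name))
  for (i in seq_len(nrow(solutes))) {
    for (j in seq_len(nrow(solvents))) {
      dd <- solutes$delta_d[i] - solvents$delta_d[j]
      dp <- solutes$delta_p[i] - solvents$delta_p[j]
      dh <- solutes$delta_h[i] - solvents$delta_h[j]
      r_solv <- (4 * dd^2 + dp^2 + dh^2)^0.5
      m[i, j] <- r_solv / solutes$r_spher[i]
    }
  }
  m
}

random_solvents <- function(n) {
  tibble::tibble(
    name = paste0("S", seq_len(n)),
    delta_d = runif(n, 13, 16),
    delta_p = runif(n, 0, 10),
    delta_h = runif(n, 0, 16)
  )
}

# a sphere strictly inside the fitting box, with margin
random_sphere <- function() {
  c(delta_d = runif(1, 12, 23), delta_p = runif(1, 1, 18),
    delta_h = runif(1, 1, 23), r_spher = runif(1, 2, 20))
}

forward_red <- function(sphere, solvents) {
  hansen_distance(sphere[["delta_d"]], sphere[["delta_p"]], sphere[["delta_h"]],
                  solvents$delta_d, solvents$delta_p, solvents$delta_h) /
    sphere[["r_spher"]]
}
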