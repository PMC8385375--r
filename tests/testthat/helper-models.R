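# shared fixtures: baseline parameters and small environment ensembles

baseline <- function(...) dd_params(...)

gaussian_ensemble <- function(n_nodes = 50, resume = "continue", ...) {
  build_ensemble(dd_environment("gaussian_stop", resume = resume, ...),
                 n_nodes = n_nodes)
}

# hand iteration of the certain-repair dynamics: every damaged cell repairs
# at step 1, repaired cells double (capped by the free space) at the end of
# every step including the one they repaired in
certain_repair_ts <- function(N0, Nmax) {
  R <- 0; D <- N0
  for (n in 1:100) {
    R <- R + D; D <- 0                       # all repair at step 1
    R <- R + min(R, Nmax - R)                # division into the free space
    if (R >= Nmax) return(n)
  }
  NA_integer_
}
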