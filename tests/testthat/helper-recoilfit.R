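# shared fixtures: noise-free series and a random-chain generator with an
# independent ODE oracle (deSolve) for the Bateman solution

LAM_BI <- decay_constant(45.6)   # Bi-213, min^-1

make_series <- function(A_eq, A0, lambda2 = LAM_BI,
                        times = seq(0, 1080, by = 10)) {
  data.frame(t_min = times,
             value = ingrowth_activity(A_eq, A0, lambda2, times))
}

random_chain <- function(n_members) {
  hl <- stats::runif(n_members, 5, 2000)  # minutes
  members <- lapply(seq_len(n_members), function(i)
    nuclide(paste0("N", i), hl[i], "min"))
  decay_chain(members)
}

# numerical ODE integration of the same linear chain (activities)
ode_chain_activities <- function(chain, initial_activities, t,
                                 unit = "min") {
  lam <- vapply(chain$members, function(x) nuclide_lambda(x, unit),
                numeric(1))
  names(lam) <- chain$names
  A0 <- setNames(numeric(length(lam)), chain$names)
  A0[names(initial_activities)] <- initial_activities
  N0 <- A0 / lam
  rhs <- function(tt, N, p) {
    dN <- -lam * N
    if (nrow(chain$edges)) for (k in seq_len(nrow(chain$edges))) {
      pa <- chain$edges$parent[k]; da <- chain$edges$daughter[k]
      dN[da] <- dN[da] + chain$edges$branching[k] * lam[pa] * N[pa]
    }
    list(dN)
  }
  sol <- deSolve::ode(N0, c(0, t), rhs, NULL, rtol = 1e-10, atol = 1e-14)
  A <- sol[-1, -1, drop = FALSE] * rep(lam, each = length(t))
  rownames(A) <- NULL
  if (length(t) == 1L) setNames(drop(A), chain$names) else t(A)
}
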