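# Shared fixture builders; everything is generated in code.

# Observer with memorability-independent parameters (constant links).
const_observer <- function(model = "dpsd", ro = 0.3, dprime = 1,
                           vo = 1, criteria = c(-1, -0.5, 0, 0.5, 1),
                           p_detailed = 0.5, subject = NULL) {
  logit_safe <- function(p) qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12))
  observer_spec(
    model = model,
    ro_link = c(logit_safe(ro), 0),
    dprime_link = c(dprime, 0),
    vo = vo,
    criteria = criteria,
    p_detailed_link = c(logit_safe(p_detailed), 0),
    subject = subject
  )
}

# Alternating old/new item list at fixed memorability.
make_items <- function(n_old, n_new, mem = 0.5) {
  n <- n_old + n_new
  tibble::tibble(
    image = sprintf("i%06d", seq_len(n)),
    memorability = mem,
    status = c(rep("old", n_old), rep("new", n_new))
  )
}

# Rating table sampled directly from model bin probabilities.
sim_counts <- function(n_old, n_new, probs) {
  rbind(old = as.vector(stats::rmultinom(1, n_old, probs[1, ])),
        new = as.vector(stats::rmultinom(1, n_new, probs[2, ])))
}

# Random valid parameter sets for property-style tests.
random_dpsd <- function() {
  list(ro = runif(1), dprime = runif(1, 0, 2.5),
       criteria = sort(rnorm(5, 0, 1)))
}

random_uvsd <- function() {
  list(dprime = runif(1, -0.5, 2.5), vo = exp(runif(1, -0.5, 0.7)),
       criteria = sort(rnorm(5, 0, 1)))
}
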