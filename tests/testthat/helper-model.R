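# Shared fixtures, built in code.

base_ps <- default_parameters()
base_lt <- default_life_table()
base_dem <- default_demography(base_ps)

# A life table with the same constant death probability at every age
flat_life_table <- function(q, age_min = 50, age_max = 99) {
  lt <- data.frame(age = seq.int(age_min, age_max), qx = q)
  class(lt) <- c("nephro_life_table", "data.frame")
  lt
}

# Parameters with all disease transitions switched off
frozen_params <- function(ps = default_parameters()) {
  ps$q_nm <- 0
  ps$q_mM <- 0
  ps$q_ME <- 0
  ps$q_esrd_death <- 0
  ps
}

# Random row-stochastic-trace generator for oracle checks: a trace over a
# handful of cycles with occupancies on the simplex
random_trace <- function(n_boundaries, age_entry = 50) {
  occ <- matrix(stats::rexp(n_boundaries * 8), n_boundaries, 8)
  occ <- occ / rowSums(occ)
  colnames(occ) <- compartments()
  attr(occ, "ages") <- seq.int(age_entry, age_entry + n_boundaries - 1)
  attr(occ, "strategy") <- "treat_all"
  class(occ) <- c("nephro_trace", class(occ))
  occ
}

# Independent brute-force accumulation: explicit loops, no shared code with
# accumulate_outcomes()
brute_force_outcomes <- function(trace, payoff_list, r_cost, r_effect) {
  n <- nrow(trace)
  cost <- 0; qaly <- 0; ly <- 0
  alive_idx <- which(compartments() != "DEAD")
  for (k in seq_len(n)) {
    w <- if (k == 1 || k == n) 0.5 else 1
    cyc <- k - 1
    c_k <- 0; q_k <- 0; l_k <- 0
    for (j in 1:8) {
      c_k <- c_k + trace[k, j] * payoff_list[[k]]$cost[j]
      q_k <- q_k + trace[k, j] * payoff_list[[k]]$utility[j]
    }
    for (j in alive_idx) l_k <- l_k + trace[k, j]
    cost <- cost + w * c_k / (1 + r_cost)^cyc
    qaly <- qaly + w * q_k / (1 + r_effect)^cyc
    ly <- ly + w * l_k
  }
  list(cost = unname(cost), qaly = unname(qaly), ly = unname(ly))
}

# Exhaustive pairwise dominance oracle over a result table
dominance_oracle <- function(res) {
  n <- nrow(res)
  vapply(seq_len(n), function(i) {
    any(vapply(seq_len(n), function(j) {
      j != i && res$cost[j] <= res$cost[i] && res$qalys[j] >= res$qalys[i] &&
        (res$cost[j] < res$cost[i] || res$qalys[j] > res$qalys[i])
    }, logical(1)))
  }, logical(1))
}
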