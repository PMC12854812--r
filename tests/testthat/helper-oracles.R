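# Independent oracles. These deliberately share no code with the
# package's solver: exhaustive subset enumeration checks optimality, and
# risk values are recomputed from the closed-form power law.

# Best achievable objective by enumerating all 2^n subsets (n <= 20).
# Returns -Inf when no subset is feasible.
brute_force_objective <- function(problem) {
  px <- problem$pixels
  n <- nrow(px)
  stopifnot(n <= 20)
  M <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  feas <- rowSums(M) <= problem$cap_n
  for (a in names(problem$min_n)) {
    feas <- feas & (M %*% (px$habitat == as.integer(a))) >= problem$min_n[[a]]
  }
  if (!is.null(problem$budget_usd)) {
    feas <- feas & (M %*% px$cost_usd) <= problem$budget_usd + 1e-9
    obj <- M %*% px$benefit
  } else {
    obj <- M %*% px$ratio
  }
  if (!any(feas)) return(-Inf)
  max(obj[feas])
}

# Chosen idx set of the best subset (tie-broken by objective then cost),
# for frozen worked-example assertions.
brute_force_selection <- function(problem) {
  px <- problem$pixels
  n <- nrow(px)
  stopifnot(n <= 20)
  M <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  feas <- rowSums(M) <= problem$cap_n
  for (a in names(problem$min_n)) {
    feas <- feas & (M %*% (px$habitat == as.integer(a))) >= problem$min_n[[a]]
  }
  obj <- as.numeric(M %*% px$ratio)
  cost <- as.numeric(M %*% px$cost_usd)
  obj[!feas] <- -Inf
  best <- which(obj > max(obj) - 1e-12)
  best <- best[which.min(cost[best])]
  sort(px$idx[M[best, ] == 1])
}

# Closed-form SAR risk, written independently of the package functions.
oracle_risk <- function(a_c, a_o, z) 1 - (a_c / a_o)^z
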