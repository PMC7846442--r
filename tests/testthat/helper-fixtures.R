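# Shared fixtures: tiny hand-built networks and an independent percentile
# oracle (direct interpolation formula, kept separate from the package path).

oracle_percentile <- function(values, q) {
  x <- sort(values)
  n <- length(x)
  if (n == 1L) return(x)
  r <- 1 + q * (n - 1) / 100
  lo <- floor(r); hi <- ceiling(r)
  x[lo] + (r - lo) * (x[hi] - x[lo])
}

oracle_ipr80 <- function(values) {
  oracle_percentile(values, 90) - oracle_percentile(values, 10)
}

# single binary A -> binary B chain: P(A=yes)=0.3, P(B=yes|A=yes)=0.9,
# P(B=yes|A=no)=0.2
chain_network <- function() {
  vars <- eb_varset(list(
    eb_variable("a", "RISK_FACTOR", "BINARY", c("no", "yes")),
    eb_variable("b", "JUDGEMENT_FACTOR", "BINARY", c("no", "yes"))))
  eb_network(
    vars,
    data.frame(from = "a", to = "b"),
    list(a = eb_cpt("a", c("no", "yes"), prob = cbind(c(0.7, 0.3))),
         b = eb_cpt("b", c("no", "yes"), "a", list(a = c("no", "yes")),
                    matrix(c(0.8, 0.2, 0.1, 0.9), 2))))
}

# small random layered network via the generator (<= 8 nodes, <= 3 states)
small_random_network <- function(seed) {
  make_ground_truth(3, 2, 3, edge_density = 0.6, seed = seed)$network
}

# unanimous stage-1 panel: every expert places every variable identically
unanimous_stage1 <- function(n_experts = 5L) {
  vars <- c("v1", "v2", "v3")
  do.call(rbind, lapply(sprintf("E%02d", seq_len(n_experts)), function(id)
    data.frame(expert_id = id, variable = vars, category = "RISK_FACTOR",
               position = seq_along(vars), list_length = length(vars),
               stringsAsFactors = FALSE)))
}
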