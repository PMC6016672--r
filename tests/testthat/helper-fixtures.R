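# Shared fixtures and independent oracles.

# --- passive compartment tables ---------------------------------------

passive_comps <- function(n, parent = c(NA, seq_len(max(n - 1, 0))),
                          len = 5, diam = 2, gl = 0.1, el = -70,
                          ra = 150, cm = 1) {
  data.frame(label = sprintf("c%03d", seq_len(n)),
             parent = as.integer(parent),
             length = rep_len(len, n), diam = rep_len(diam, n),
             x = cumsum(rep_len(len, n)) - rep_len(len, n) / 2,
             cm = cm, ra = ra, g_leak = gl, e_leak = el,
             g_na = 0, g_kdr = 0, g_ka = 0, g_ca = 0,
             stringsAsFactors = FALSE)
}

random_tree_graph <- function(n, seed) {
  set.seed(seed)
  parent <- c(NA_integer_,
              vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L))
  comps <- passive_comps(n, parent = parent,
                         len = runif(n, 2, 20),
                         diam = runif(n, 0.5, 5),
                         gl = runif(1, 0.02, 0.3))
  compartment_graph(comps)
}

# --- dense backward-Euler oracle (passive trees) ----------------------

# One implicit-Euler step solved with a dense LU factorisation; the
# package solves the same linear system by tree elimination.
dense_be_step <- function(v, graph, dt, inj_nA = numeric(graph$n)) {
  df <- as.data.frame(graph)
  n <- graph$n
  A <- matrix(0, n, n)
  gl <- df$g_leak * df$area_cm2
  cm <- df$cm * df$area_cm2
  diag(A) <- cm / dt + gl
  b <- cm / dt * v + gl * df$e_leak + inj_nA * 1e-3
  if (n > 1) {
    for (i in 2:n) {
      p <- df$parent[i]
      g <- df$g_axial_mS[i]
      A[i, i] <- A[i, i] + g
      A[p, p] <- A[p, p] + g
      A[i, p] <- A[i, p] - g
      A[p, i] <- A[p, i] - g
    }
  }
  as.numeric(solve(A, b))
}

# --- exact Wilcoxon enumeration oracle --------------------------------

wilcoxon_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 12)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  W <- as.numeric(signs %*% r)
  eps <- 1e-9
  min(1, 2 * min(mean(W <= w + eps), mean(W >= w - eps)))
}

# --- cached standard model fixtures (built on first use) --------------

.fixtures <- new.env(parent = emptyenv())

std_cond <- function() {
  if (is.null(.fixtures$cond)) .fixtures$cond <- setup_condition(70)
  .fixtures$cond
}

std_trials <- function() {
  if (is.null(.fixtures$trials)) {
    cond <- std_cond()
    types <- c("bAP", "IPSP-bAP", "IPSP")
    .fixtures$trials <- setNames(
      lapply(types, function(ty) run_trial(protocol_spec(ty), cond)),
      types)
  }
  .fixtures$trials
}
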