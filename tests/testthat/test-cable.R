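# Morphology construction and the backward-Euler cable solver.

test_that("compartment_graph validates geometry and topology", {
  comps <- passive_comps(4)
  expect_s3_class(compartment_graph(comps), "compartment_graph")
  bad <- comps; bad$diam[2] <- -1
  expect_error(compartment_graph(bad), "invalid geometry")
  bad <- comps; bad$length[3] <- 0
  expect_error(compartment_graph(bad), "invalid geometry")
  bad <- comps; bad$parent[3] <- 5L  # forward reference
  expect_error(compartment_graph(bad), "parents")
  bad <- comps; bad$parent[1] <- 2L  # no root
  expect_error(compartment_graph(bad), "root")
  expect_error(compartment_graph(comps[, -3]), "missing columns")
})

test_that("the standard model has the study geometry", {
  g <- build_model()
  df <- as.data.frame(g)
  trunk <- df[grepl("^trunk", df$label), ]
  expect_equal(nrow(trunk), 100)
  expect_true(all(trunk$length == 5))
  expect_equal(sum(trunk$length), 500)
  neck <- df[df$label == "spine_neck", ]
  expect_equal(neck$length, 1)
  expect_equal(neck$diam, 0.07)
  expect_equal(df[df$label == "spine_head", "diam"], 1)
  # tree: every non-root compartment has exactly one parent edge
  expect_equal(sum(!is.na(df$parent)), nrow(df) - 1L)
  # synapse on the trunk at 122.5 um with the printed A-type density
  syn <- df[g$synapse_comp, ]
  expect_equal(syn$x, 122.5)
  expect_equal(syn$g_ka, 17.0, tolerance = 0.05)
  # calcium reporter only in the spine head and neighbouring shaft
  expect_setequal(df$label[df$g_ca > 0], c("spine_head", syn$label))
  expect_error(build_model(trunk_diam = -2), "invalid geometry")
})

test_that("a passive model at its leak reversal stays put", {
  g <- compartment_graph(passive_comps(10))
  st <- init_state(g, v = -70)
  st2 <- solver_step(st, g, 0.005)
  expect_lt(max(abs(st2$v - (-70))), 1e-12)
  tr <- simulate(g, solver_config(1), init = st)
  expect_lt(max(abs(tr$v[[1]] - (-70))), 1e-10)
})

test_that("a single passive compartment follows the RC closed form", {
  comps <- passive_comps(1, parent = NA_integer_, gl = 0.1)
  g <- compartment_graph(comps)
  tr <- simulate(g, solver_config(30), init = init_state(g, v = -55))
  tau <- comps$cm / comps$g_leak  # ms
  exact <- -70 + (-55 + 70) * exp(-tr$time / tau)
  expect_lt(max(abs(tr$v[[1]] - exact)), 0.01)
})

test_that("a passive pair matches the matrix-exponential oracle", {
  comps <- passive_comps(2, len = c(10, 4), diam = c(3, 1), gl = 0.08)
  g <- compartment_graph(comps)
  df <- as.data.frame(g)
  cm <- df$cm * df$area_cm2
  gl <- df$g_leak * df$area_cm2
  gax <- df$g_axial_mS[2]
  A <- rbind(c(-(gl[1] + gax) / cm[1], gax / cm[1]),
             c(gax / cm[2], -(gl[2] + gax) / cm[2]))
  v0 <- c(-50, -70)
  vinf <- c(-70, -70)
  ev <- eigen(A)
  expmAt <- function(t) ev$vectors %*% diag(exp(ev$values * t)) %*%
    solve(ev$vectors)
  tr <- simulate(g, solver_config(5, record_v = df$label),
                 init = {
                   st <- init_state(g); st$v <- v0; st
                 })
  for (t_chk in c(1, 3, 5)) {
    i <- which.min(abs(tr$time - t_chk))
    exact <- vinf + as.numeric(expmAt(tr$time[i]) %*% (v0 - vinf))
    expect_lt(max(abs(c(tr$v[[1]][i], tr$v[[2]][i]) - exact)), 0.05)
  }
})

test_that("tree elimination equals a dense solve on small random trees", {
  for (seed in 1:10) {
    n <- sample(2:12, 1)
    g <- random_tree_graph(n, seed = seed)
    st <- init_state(g, v = -60)
    st$v <- st$v + runif(n, -15, 15)
    inj <- numeric(n); inj[sample.int(n, 1)] <- 0.05  # nA
    for (k in 1:20) {
      v_dense <- dense_be_step(st$v, g, 0.005, inj_nA = inj)
      st <- solver_step(st, g, 0.005, i_inj = inj)
      expect_lt(max(abs(st$v - v_dense)), 1e-10)
    }
  }
})

test_that("compiled and R reference steppers agree", {
  g <- build_model()
  n <- g$n
  st <- init_state(g)
  cfg <- solver_config(1, record_v = "soma")
  stim <- stim_pulse(0.2, 0.5, 2)
  tr <- simulate(g, cfg, stimuli = stim, synapse = NULL, init = st,
                 rate_tables = FALSE)
  st_r <- st
  for (k in 1:200) {
    inj <- numeric(n)
    t_new <- k * 0.005
    if (t_new > 0.2 + 1e-12 && t_new <= 0.7 + 1e-12) inj[1] <- 2
    st_r <- solver_step(st_r, g, 0.005, i_inj = inj)
  }
  expect_equal(tail(tr$v$soma, 1), st_r$v[1], tolerance = 1e-10)
  expect_lt(max(abs(tr$final_state$v - st_r$v)), 1e-9)
  expect_lt(max(abs(tr$final_state$gates - st_r$gates)), 1e-9)
})

test_that("rate tables track the exact kinetics closely", {
  g <- build_model()
  cfg <- solver_config(40, record_v = c("soma", "trunk_025"))
  stim <- list(stim_pulse(0, 40, 0.05), stim_pulse(10, 0.5, 2.4))
  t1 <- simulate(g, cfg, stimuli = stim, rate_tables = TRUE)
  t2 <- simulate(g, cfg, stimuli = stim, rate_tables = FALSE)
  expect_lt(max(abs(t1$v$trunk_025 - t2$v$trunk_025)), 1e-4)
})

test_that("passive steady-state attenuation matches the finite cable", {
  comps <- passive_comps(100, len = 5, diam = 2, gl = 0.1)
  g <- compartment_graph(comps)
  tr <- simulate(g, solver_config(200, record_v = comps$label,
                                  sample_every = 8000),
                 stimuli = stim_pulse(0, 200, 0.02, target = 1L),
                 init = init_state(g, v = -70))
  v_end <- vapply(tr$v, function(x) tail(x, 1), 0) + 70
  lambda <- sqrt((1 / comps$g_leak[1]) * 1e3 * (comps$diam[1] * 1e-4) /
                   (4 * comps$ra[1])) * 1e4  # um
  x <- comps$x
  L <- sum(comps$length)
  prof <- cosh((L - x) / lambda) / cosh((L - x[1]) / lambda)
  ratio <- v_end / v_end[1]
  expect_lt(max(abs(ratio - prof) / prof), 0.01)
})

test_that("with no stimulus the passive voltage decays monotonically to E_leak", {
  g <- compartment_graph(passive_comps(20))
  for (v0 in c(-40, -90)) {
    tr <- simulate(g, solver_config(60, record_v = c("c001", "c020"),
                                    sample_every = 100),
                   init = init_state(g, v = v0))
    for (s in names(tr$v)) {
      dv <- diff(tr$v[[s]])
      if (v0 > -70) expect_true(all(dv <= 1e-12)) else
        expect_true(all(dv >= -1e-12))
      expect_equal(tail(tr$v[[s]], 1), -70, tolerance = 0.05)
    }
  }
})

test_that("simulate is bit-reproducible and duration 0 returns the start", {
  g <- build_model()
  cfg <- solver_config(5, record_v = "soma")
  a <- simulate(g, cfg, stimuli = stim_pulse(1, 0.5, 2))
  b <- simulate(g, cfg, stimuli = stim_pulse(1, 0.5, 2))
  expect_identical(a$v$soma, b$v$soma)
  z <- simulate(g, solver_config(0, record_v = "soma"))
  expect_equal(length(z$time), 1L)
  expect_equal(z$v$soma, -64)
})
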