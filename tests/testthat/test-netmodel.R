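test_that("synaptic weight follows the group normalization rule", {
  expect_equal(synaptic_weight(5, 0.36, 1062, 0.16), 5 * 0.36 / (1062 * 0.16))
  expect_equal(synaptic_weight(5, 0.36, 1062, 0.16), 0.0105932, tolerance = 1e-5)
  expect_equal(synaptic_weight(5, 0.48, 188, 0.411), 0.031061, tolerance = 1e-4)
  expect_equal(synaptic_weight(7, 0, 500, 0.2), 0)
  expect_error(synaptic_weight(5, 0.3, 0, 0.2), "undefined normalization")
  expect_error(synaptic_weight(5, 0.3, 100, 0), "undefined normalization")
})

test_that("doubling the sending population exactly halves the weight", {
  for (k in 1:20) {
    set.seed(k)
    g <- runif(1, 1, 60); s <- runif(1); n <- sample(10:5000, 1)
    p <- runif(1, 0.05, 1)
    expect_equal(synaptic_weight(g, s, 2 * n, p),
                 synaptic_weight(g, s, n, p) / 2)
  }
})

test_that("connectome respects group sizes and wiring constraints", {
  con <- default_connectome()
  u <- con$units
  counts <- table(u$area, u$type)
  expect_true(all(counts[, "E"] == 1062))
  expect_true(all(counts[, "I"] == 188))

  # inhibitory neurons never project outside their own area
  W <- methods::as(con$W, "CsparseMatrix")
  src <- rep(seq_len(nrow(u)), diff(W@p))
  tgt <- W@i + 1L
  inter <- u$area[src] != u$area[tgt]
  expect_true(all(u$type[src[inter]] == "E"))
  # and inter-areal weights are the scaled Table entries for their area pair
  w12 <- W@x[inter & u$area[src] == 1 & u$area[tgt] == 2]
  expect_true(all(w12 == 50 * 6.93e-4))

  # within-area weights all equal the group value where a synapse exists
  a1E <- u$unit_id[u$area == 1 & u$type == "E"]
  in_block <- src %in% a1E & tgt %in% a1E
  expect_true(all(abs(W@x[in_block] - synaptic_weight(5, 0.36, 1062, 0.16))
                  < 1e-12))
  # E -> E synapse count is binomial around 1062^2 * 0.16
  n_pairs <- 1062 * 1062 - 1062  # self-synapses excluded
  expected <- n_pairs * 0.16
  expect_lt(abs(sum(in_block) - expected), 6 * sqrt(expected * 0.84))
})

test_that("connectome realization is reproducible from its seed", {
  a <- build_connectome(small_arch(), seed = 11)
  b <- build_connectome(small_arch(), seed = 11)
  expect_identical(a$W@x, b$W@x)
  expect_identical(a$W@i, b$W@i)
})

test_that("no drive produces no spikes", {
  con <- build_connectome(small_arch(), seed = 2)
  ras <- simulate_network(con, duration_s = 0.3, seed = 3,
                          kinetics = synapse_kinetics(u_bkgnd_E = 0,
                                                      u_bkgnd_I = 0))
  expect_equal(nrow(ras$spikes), 0)
})

test_that("an isolated neuron under constant current matches the closed-form LIF rate", {
  units <- data.frame(unit_id = 1L, area = 1L, type = "E")
  con <- structure(list(W = Matrix::sparseMatrix(i = 1, j = 1, x = 0,
                                                 dims = c(1, 1)),
                        units = units, arch = NULL, seed = 0L),
                   class = "connectome")
  p <- neuron_params_E()
  I <- 150  # pA, above rheobase g_L * (V_th - V_rest) = 99.9 pA
  ras <- simulate_network(con, duration_s = 5,
                          stimulus = stimulus_protocol(1, I, 0, 5),
                          seed = 2,
                          kinetics = synapse_kinetics(u_bkgnd_E = 0,
                                                      u_bkgnd_I = 0))
  t_m <- p$C_m / p$g_L / 1000  # s
  period <- p$t_ref / 1000 +
    t_m * log((I / p$g_L) / (I / p$g_L - (p$V_th - p$V_rest)))
  expect_equal(nrow(ras$spikes) / 5, 1 / period, tolerance = 0.03)
})

test_that("no unit ever violates its refractory period", {
  ras <- demo_raster()
  tref <- ifelse(ras$units$type == "E", 3, 1.26) / 1000
  by_unit <- split(ras$spikes$time_s, ras$spikes$unit_id)
  ok <- vapply(names(by_unit), function(id) {
    isi <- diff(sort(by_unit[[id]]))
    length(isi) == 0 ||
      min(isi) >= tref[ras$units$unit_id == as.integer(id)] - 1e-9
  }, logical(1))
  expect_true(all(ok))
})

test_that("current injection into R1 propagates most strongly to R2", {
  ras <- demo_raster()
  pre <- area_rates(ras, 0.3, 1.0)
  post <- area_rates(ras, 1.0, 1.7)
  jump <- post - pre
  expect_equal(which.max(jump), c(R1 = 1))
  expect_equal(which.max(jump[-1]), c(R2 = 1))
})

test_that("with all synapses silenced the areas are statistically exchangeable", {
  arch <- small_arch()
  arch$S_within <- matrix(0, 2, 2, dimnames = dimnames(arch$S_within))
  arch$W_between <- matrix(0, 4, 4)
  con <- build_connectome(arch, seed = 9)
  ras <- simulate_network(con, duration_s = 1, seed = 10)
  u <- ras$units
  counts <- tabulate(ras$spikes$unit_id, nbins = nrow(u))
  rates_E <- split(counts[u$type == "E"], u$area[u$type == "E"])
  kw <- kruskal.test(rates_E)
  expect_gt(kw$p.value, 0.001)
})

test_that("simulation is byte-for-byte reproducible from its seeds", {
  con <- build_connectome(small_arch(), seed = 5)
  a <- simulate_network(con, duration_s = 0.4, seed = 6)
  b <- simulate_network(con, duration_s = 0.4, seed = 6)
  expect_identical(a$spikes, b$spikes)
})
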