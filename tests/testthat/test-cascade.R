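# Cascade (MFE) resolution at a single instant.

test_that("a spike too weak to recruit anyone gives a magnitude-1 cascade", {
  n <- 5
  W <- matrix(0.5, n, n); diag(W) <- 0
  V <- c(1, rep(0.4, n - 1))          # jumps of ~0.1 cannot reach threshold
  r <- resolveCascade(V, rep("E", n), W, initiators = 1)
  expect_identical(magnitude(r), 1L)
  expect_identical(r@order, 1L)
  # targets moved up but stayed below threshold
  expect_true(all(r@Vpost[-1] > 0.4 & r@Vpost[-1] < 1))
})

test_that("recruitment and inhibitory termination follow the fast-synapse limit", {
  # E1 fires; E2 and I3 cross on E1's kernel; I3 (closer to threshold)
  # fires first and its inhibition can abort E2's crossing; E4 is suppressed.
  pop <- c("E", "E", "I", "E")
  W <- matrix(0, 4, 4)
  W[2, 1] <- 0.5; W[3, 1] <- 0.5; W[4, 1] <- 0.05
  W[2, 3] <- 2; W[4, 3] <- 2
  V <- c(1, 0.99, 0.995, 0.98)
  r <- resolveCascade(V, pop, W, initiators = 1)
  o <- finiteTauCascade(V, pop, W, 1e-4)
  expect_identical(r@order, o$order)
  # the suppressed E neuron ends below where it started
  expect_lt(r@Vpost[4], 0.98)
  expect_true(all(abs(r@Vpost[-r@order] - o$V[-o$order]) < 1e-3))
})

test_that("cascade fired sets equal brute-force finite-tau simulation", {
  set.seed(101)
  for (cs in 1:60) {
    n <- sample(2:6, 1)
    pop <- sample(c("E", "I"), n, replace = TRUE)
    V <- runif(n, -2 / 3, 0.999)
    init <- sample.int(n, 1)
    V[init] <- 1
    W <- matrix(rexp(n * n, 1 / 0.6), n, n) * (runif(n * n) < 0.8)
    diag(W) <- 0
    r <- resolveCascade(V, pop, W, initiators = init)
    o <- finiteTauCascade(V, pop, W, 1e-3)
    expect_identical(sort(r@order), sort(o$order))
  }
})

test_that("each neuron fires at most once per instant", {
  set.seed(202)
  for (cs in 1:200) {
    n <- sample(3:10, 1)
    pop <- sample(c("E", "I"), n, replace = TRUE)
    V <- runif(n, 0, 0.999)
    init <- sample.int(n, 1)
    V[init] <- 1
    # strong all-to-all excitation: try to provoke re-firing
    W <- matrix(rexp(n * n, 1 / 3), n, n)
    diag(W) <- 0
    r <- resolveCascade(V, pop, W, initiators = init)
    expect_false(anyDuplicated(r@order) > 0)
    expect_lte(magnitude(r), n)
    expect_gte(magnitude(r), 1L)
  }
})

test_that("non-firing neurons with I-dominated input are pushed down", {
  # the nonfiring population is suppressed when the conductance-weighted
  # equilibrium (wE V_E + wI V_I)/(wE + wI) of its input lies well below
  # its voltage (with conductance synapses, equal weights do NOT mean equal
  # pull: the drive toward each reversal scales with the distance to it)
  p <- neuronParams()
  set.seed(303)
  for (cs in 1:30) {
    pop <- c("E", "I", "E")          # E1 fires, recruits I2; E3 observes
    W <- matrix(0, 3, 3)
    W[2, 1] <- 3                      # E1 -> I2, guarantees recruitment
    V3 <- runif(1, 0.3, 0.9)
    wE <- runif(1, 0.02, 0.2)
    # choose wI so the joint input equilibrium sits well below V3
    wI <- wE * (p@VE - V3) / (V3 - p@VI) * runif(1, 2.5, 5)
    W[3, 1] <- wE; W[3, 2] <- wI
    V <- c(1, 0.9, V3)
    r <- resolveCascade(V, pop, W, initiators = 1)
    expect_setequal(r@order, c(1L, 2L))
    expect_lte(r@Vpost[3], r@Vpre[3] + 1e-9)
  }
})

test_that("slow increments are withheld from fired and refractory neurons", {
  pop <- c("E", "E", "E")
  Wf <- matrix(0, 3, 3); Wf[2, 1] <- 2; Wf[3, 1] <- 0.1
  Ws <- matrix(0, 3, 3); Ws[2, 1] <- 1; Ws[3, 1] <- 1
  V <- c(1, 0.99, 0.2)
  r <- resolveCascade(V, pop, Wf, Ws, initiators = 1)
  expect_setequal(r@order, c(1L, 2L))
  expect_identical(r@slowPending[2], 0)   # fired -> refractory at instant end
  expect_identical(r@slowPending[3], 1)
  # blocked neurons receive nothing and cannot fire
  rb <- resolveCascade(V, pop, Wf, Ws, initiators = 1,
                       blocked = c(FALSE, TRUE, FALSE))
  expect_identical(rb@order, 1L)
  expect_identical(rb@slowPending[2], 0)
  expect_identical(rb@Vpost[2], 0.99)
})
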