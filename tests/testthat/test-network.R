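# Architecture construction and validation.

test_that("default geometry yields 24 clusters of 256 neurons", {
  g <- networkGeometry()
  expect_identical(nClusters(g), 24L)
  expect_identical(nNeurons(g), 6144L)
})

test_that("build is reproducible and respects the zero-structure", {
  g <- networkGeometry(3, 2, 24, 24)
  n1 <- buildNetwork(g, seed = 5)
  n2 <- buildNetwork(g, seed = 5)
  expect_identical(Matrix::summary(fastWeights(n1)),
                   Matrix::summary(fastWeights(n2)))
  n3 <- buildNetwork(g, seed = 6)
  expect_false(identical(Matrix::summary(fastWeights(n1)),
                         Matrix::summary(fastWeights(n3))))
  v <- validateNetwork(n1)
  expect_true(v$ok)
  expect_length(v$failures, 0)
})

test_that("single-cluster geometry has no long-range or cross entries", {
  net <- buildNetwork(networkGeometry(1, 1, 30, 30), seed = 2)
  v <- validateNetwork(net)
  expect_true(v$ok)
  expect_setequal(v$report$relation, "local")
})

test_that("empirical connection fractions track the configured probabilities", {
  cv <- connectivityParams()
  nets <- lapply(1:3, function(s)
    buildNetwork(networkGeometry(2, 2, 128, 128), cv, seed = s))
  for (net in nets) {
    rp <- validateNetwork(net)$report
    dev <- abs(rp$fraction - rp$configured) / rp$se
    expect_true(all(dev < 4))
  }
  fr <- localConnectionFractions(nets[[1]])
  expect_equal(unname(fr["E"]), 0.20, tolerance = 0.05)
  expect_equal(unname(fr["I"]), 0.50, tolerance = 0.03)
})

test_that("weights are homogeneous within a class and scale as configured", {
  cv <- connectivityParams()
  net <- buildNetwork(networkGeometry(2, 2, 32, 32), cv, seed = 9)
  nt <- neuronTable(net)
  tf <- Matrix::summary(fastWeights(net))
  ts <- Matrix::summary(slowWeights(net))
  sType <- nt$type[tf$j]; rType <- nt$type[tf$i]
  sameK <- nt$k[tf$j] == nt$k[tf$i]
  # local fast E->E weight equals sFast["E","E"] everywhere
  sel <- sameK & sType == "E" & rType == "E"
  expect_true(all(tf$x[sel] == cv@sFast["E", "E"]))
  # long-range rows use the L strengths
  selL <- !sameK & rType == "I"
  expect_true(all(tf$x[selL] == cv@lFast[2]))
  expect_true(all(ts$x[selL] == cv@lSlow[2]))
  # I senders have zero slow weight everywhere
  expect_true(all(ts$x[sType == "I"] == 0))
})

test_that("an illegal hand-built edge is flagged by name", {
  net <- buildNetwork(networkGeometry(2, 1, 2, 2), seed = 1)
  nt <- neuronTable(net)
  iSender <- nt$id[nt$type == "I" & nt$k == 1][1]
  rcv <- nt$id[nt$k == 2][1]
  Wf <- as(fastWeights(net), "TsparseMatrix")
  n <- nNeurons(net)
  Wbad <- Matrix::sparseMatrix(i = c(Wf@i + 1L, rcv), j = c(Wf@j + 1L, iSender),
                               x = c(Wf@x, 0.5), dims = c(n, n))
  netBad <- net
  netBad@Wfast <- Wbad
  netBad@Wslow <- Matrix::sparseMatrix(i = c(Wf@i + 1L, rcv),
                                       j = c(Wf@j + 1L, iSender),
                                       x = c(slowWeights(net)@x, 0),
                                       dims = c(n, n))
  v <- validateNetwork(netBad)
  expect_false(v$ok)
  expect_true(any(grepl("hypercolumn", v$failures)))
})

test_that("network text serialization round-trips bit-exactly", {
  net <- buildNetwork(networkGeometry(2, 2, 12, 12),
                      connectivityParams(sFast = matrix(c(0.11, 0.13,
                                                          1 / 3, 0.29), 2, 2),
                                         delay = 2.5),
                      seed = 7)
  pre <- file.path(tempdir(), "net-roundtrip")
  writeNetwork(net, pre)
  net2 <- readNetwork(pre)
  expect_identical(neuronTable(net2), neuronTable(net))
  expect_true(identical(Matrix::summary(fastWeights(net)),
                        Matrix::summary(fastWeights(net2))))
  expect_true(identical(slowWeights(net)@x, slowWeights(net2)@x))
  expect_identical(net2@connectivity@delay, 2.5)
  expect_identical(net2@connectivity@sFast[1, 2], 1 / 3)
})
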