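# Gate semantics, linearization, contribution weights, and the greedy
# feedback optimizers against the exhaustive oracle.

test_that("feedforward gates reproduce the trace and the forward output", {
  net <- micro_net(1)
  tr <- net_forward(net, rand_image(2))
  g <- gates_from_trace(tr)
  expect_equal(g$provenance, "feedforward")
  # gate = 1 iff pre-activation strictly positive (zero closes)
  netr <- net_build(list(relu_layer()), c(1L, 3L, 1L), seed = 1)
  trr <- net_forward(netr, c(-1, 0, 2))
  expect_equal(gates_from_trace(trr)$relu[[1L]], c(0, 0, 1))
  # all-positive activations give all-open gates
  netp <- net_build(list(relu_layer()), c(1L, 3L, 1L), seed = 1)
  expect_equal(gates_from_trace(net_forward(netp, c(1, 2, 3)))$relu[[1L]],
               c(1, 1, 1))
})

test_that("gated forward with feedforward gates equals forward exactly", {
  for (s in 1:8) {
    net <- micro_net(s)
    img <- rand_image(100 + s)
    tr <- net_forward(net, img)
    gf <- gated_forward(net, img, gates_from_trace(tr))
    expect_identical(gf$output, tr$output)
  }
})

test_that("closed gates block all signal and hand-set gates match hand math", {
  net <- zero_biases(micro_net(2))
  img <- rand_image(3)
  gates <- gates_from_trace(net_forward(net, img))
  for (l in c(2L, 5L)) gates$relu[[l]] <- gates$relu[[l]] * 0
  gf <- gated_forward(net, img, gates)
  expect_equal(gf$logit, c(0, 0, 0))

  # 2-layer hand computation: y = w2 * (z * (w1 * x)) on a 1-pixel chain
  chain <- net_build(list(dense_layer(1L), relu_layer(), dense_layer(1L)),
                     c(1L, 1L, 1L), seed = 1)
  chain <- set_dense(chain, 1L, 2)
  chain <- set_dense(chain, 3L, 5)
  g <- gates_from_trace(net_forward(chain, -3))   # pre-activation -6, gate closed
  expect_equal(gated_forward(chain, -3, g)$output, 0)
  g$relu[[2L]] <- 1                               # force the gate open
  expect_equal(gated_forward(chain, -3, g)$output, 5 * (2 * -3))  # passes -6
  expect_error(gated_forward(chain, -3,
                             structure(list(relu = vector("list", 3L),
                                            pool = vector("list", 3L),
                                            provenance = "manual"),
                                       class = "fbcnn_gates")),
               "wrong shape")
})

test_that("the frozen-switch network is affine and its gradients are exact", {
  net <- micro_net(6)
  img <- rand_image(7)
  gates <- gates_from_trace(net_forward(net, img))
  lin <- linearize(net, img, gates)
  tgt <- 2L

  # value at the anchor equals the gated forward logit
  expect_identical(lin_value(lin, target_index = tgt),
                   gated_forward(net, img, gates)$logit[tgt])

  # zero-bias homogeneity: doubling the input doubles the logit
  netz <- zero_biases(net)
  linz <- linearize(netz, img, gates)
  expect_equal(lin_value(linz, 2 * img, tgt), 2 * lin_value(linz, img, tgt),
               tolerance = 1e-12)

  # affine exactness: value at random probes equals first-order expansion
  g0 <- as.numeric(gradient_map(net, img, gates, tgt))
  v0 <- lin_value(lin, target_index = tgt)
  for (s in 1:5) {
    probe <- rand_image(200 + s)
    expect_equal(lin_value(lin, probe, tgt),
                 v0 + sum(g0 * (as.numeric(probe) - as.numeric(img))),
                 tolerance = 1e-10)
  }

  # gradient of the frozen network matches finite differences
  fd <- fd_gradient(function(x) lin_value(lin, matrix(x, 4, 4), tgt),
                    as.numeric(img))
  expect_lt(max(abs(g0 - fd)) / max(abs(fd), 1e-12), 1e-4)
})

test_that("contribution weights are pathway products of weights", {
  # two paths from a middle neuron to the target: w1*w3 + w2*w4 = 2*1 + 3*4
  net <- net_build(list(dense_layer(1L), relu_layer(), dense_layer(2L),
                        relu_layer(), dense_layer(1L)),
                   c(1L, 1L, 1L), seed = 1)
  net <- set_dense(net, 1L, 1)
  net <- set_dense(net, 3L, c(2, 3))
  net <- set_dense(net, 5L, c(1, 4))
  gates <- gates_from_trace(net_forward(net, 1))
  lin <- linearize(net, 1, gates)
  cw <- contributions(lin, 2L, 1L)
  expect_equal(cw$alpha, 14)
  # finite-difference check of the same quantity on the gated input side
  expect_equal(cw$x, 1)

  # single chain y = 5 * z * x
  chain <- net_build(list(dense_layer(1L), relu_layer(), dense_layer(1L)),
                     c(1L, 1L, 1L), seed = 1)
  chain <- set_dense(chain, 1L, 1)
  chain <- set_dense(chain, 3L, 5)
  gc <- gates_from_trace(net_forward(chain, 2))
  expect_equal(contributions(linearize(chain, 2, gc), 2L, 1L)$alpha, 5)

  # a neuron whose every upward gate is closed contributes nothing
  g2 <- gates_from_trace(net_forward(net, 1))
  g2$relu[[4L]] <- c(0, 0)
  expect_equal(contributions(linearize(net, 1, g2), 2L, 1L)$alpha, 0)

  # only rectifier layers are feedback layers
  expect_error(contributions(lin, 1L, 1L), "not a feedback")
})

test_that("the objective is the gated logit and expands as sum(alpha*z*x)", {
  net <- zero_biases(micro_net(9))
  img <- rand_image(10)
  tr <- net_forward(net, img)
  ff <- gates_from_trace(tr)
  tgt <- 1L

  # feedforward gates: objective equals the plain forward logit
  expect_identical(feedback_objective(net, img, ff, tgt),
                   tr$layers[[6L]]$y[tgt])

  # arbitrary gates: equals the hand expansion at every feedback layer
  gates <- ff
  gates$relu[[2L]] <- withr::with_seed(1, sample(0:1, 8, replace = TRUE))
  gates$relu[[5L]] <- withr::with_seed(2, sample(0:1, 4, replace = TRUE))
  S <- feedback_objective(net, img, gates, tgt)
  lin <- linearize(net, img, gates)
  for (l in c(2L, 5L)) {
    cw <- contributions(lin, l, tgt)
    expect_equal(S, sum(cw$alpha * gates$relu[[l]] * cw$x), tolerance = 1e-12)
  }

  # all gates closed with a zero-bias head: objective 0
  gates$relu[[2L]] <- rep(0, 8)
  gates$relu[[5L]] <- rep(0, 4)
  expect_equal(feedback_objective(net, img, gates, tgt), 0)
})

test_that("FR and FS keep positive contributions and never lose objective", {
  # a single feedback layer with all contributions positive changes nothing
  net <- net_build(list(dense_layer(2L), relu_layer(), dense_layer(1L)),
                   c(1L, 2L, 1L), seed = 1)
  net <- set_dense(net, 1L, diag(2))
  net <- set_dense(net, 3L, c(2, 3))
  pr <- feedback_problem(net, c(1, 2), 1L)
  fr <- feedback_recovery(pr)
  expect_equal(fr$gates$relu[[2L]], c(1, 1))
  expect_true(fr$converged)
  expect_equal(fr$sweeps_used, 1L)
  expect_equal(unique(fr$objective_trajectory), fr$initial_objective)

  # FR == FS when there is only one feedback layer
  fs <- feedback_selective(pr)
  expect_identical(fr$gates$relu, fs$gates$relu)

  # an all-positive-weight network never closes a gate under FS
  netp <- micro_net(21)
  for (i in seq_along(netp$params)) {
    if (!is.null(netp$params[[i]])) {
      netp$params[[i]]$W <- abs(netp$params[[i]]$W)
      netp$params[[i]]$b <- abs(netp$params[[i]]$b)
    }
  }
  imgp <- abs(rand_image(22))
  fsp <- feedback_selective(feedback_problem(netp, imgp, 2L))
  ffp <- gates_from_trace(net_forward(netp, imgp))
  expect_identical(fsp$gates$relu, ffp$relu)
})

test_that("FR/FS trajectories are monotone and bounded by the oracle", {
  for (s in 1:10) {
    net <- micro_net(s)
    img <- rand_image(300 + s)
    pr <- feedback_problem(net, img, 2L)
    ff <- gates_from_trace(net_forward(net, img))
    S0 <- feedback_objective(net, img, ff, 2L)
    bf <- brute_force_gate_search(pr)
    expect_gte(bf$objective, S0)
    for (res in list(feedback_recovery(pr), feedback_selective(pr))) {
      traj <- c(res$initial_objective, res$objective_trajectory)
      expect_true(all(diff(traj) >= -1e-10))
      expect_true(res$converged)
      final <- traj[length(traj)]
      expect_gte(final, S0 - 1e-10)
      expect_lte(final, bf$objective + 1e-10)
    }
  }
})

test_that("greedy optimizers reach the optimum on separable instances", {
  for (s in 1:6) {
    net <- micro_net_single(s)
    img <- rand_image(400 + s)
    pr <- feedback_problem(net, img, 1L)
    bf <- brute_force_gate_search(pr)
    for (res in list(feedback_recovery(pr), feedback_selective(pr))) {
      expect_equal(res$objective_trajectory[length(res$objective_trajectory)],
                   bf$objective, tolerance = 1e-12)
    }
  }
})

test_that("the exhaustive oracle enforces its budget and sign rule", {
  net <- micro_net(2)
  pr <- feedback_problem(net, rand_image(2), 1L)
  expect_error(brute_force_gate_search(pr, gate_budget = 4L), "12 gates")

  # one gate: open iff it helps
  chain <- net_build(list(dense_layer(1L), relu_layer(), dense_layer(1L)),
                     c(1L, 1L, 1L), seed = 1)
  chain <- set_dense(chain, 1L, 1)
  chain <- set_dense(chain, 3L, 3)
  bf_pos <- brute_force_gate_search(feedback_problem(chain, 2, 1L))
  expect_equal(bf_pos$gates$relu[[2L]], 1L)
  bf_neg <- brute_force_gate_search(feedback_problem(chain, -2, 1L))
  expect_equal(bf_neg$gates$relu[[2L]], 0L)

  # separable layer: the optimum is the per-gate sign rule
  net1 <- micro_net_single(3)
  img1 <- rand_image(5)
  bf <- brute_force_gate_search(feedback_problem(net1, img1, 1L))
  cw <- contributions(linearize(net1, img1,
                                gates_from_trace(net_forward(net1, img1))), 2L, 1L)
  expect_equal(as.numeric(bf$gates$relu[[2L]]), as.numeric(cw$alpha * cw$x > 0))
})

test_that("gate serialization round-trips and problems validate inputs", {
  net <- micro_net(4)
  g <- gates_from_trace(net_forward(net, rand_image(4)))
  path <- withr::local_tempfile(fileext = ".rds")
  gates_save(g, path)
  expect_identical(gates_load(path), g)
  expect_error(feedback_problem(net, rand_image(4), 99L), "out of range")
  expect_error(feedback_problem(net, rand_image(4), 1L, max_sweeps = 0L),
               "max_sweeps")
})
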