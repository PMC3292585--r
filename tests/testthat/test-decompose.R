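test_that("class references are feature-wise means with exclusions", {
  ds <- expression_dataset(rbind(c(1, 2), c(3, 4), c(10, 20)),
                           c(1, 1, -1), sample_ids = c("a", "b", "c"))
  expect_equal(build_reference(ds, 1), c(2, 3))
  expect_equal(build_reference(ds, -1), c(10, 20))  # single-sample class
  expect_equal(build_reference(ds, 1, exclude_ids = "a"), c(3, 4))
  expect_error(build_reference(ds, -1, exclude_ids = "c"), "no samples")
})

test_that("decomposing a constructed mixture recovers the true angles", {
  mix <- tone_mixture(c(15, 75))
  dec <- decompose_sample(mix$rows[1, ], mix$rows[2, ], M = 2,
                          delta_theta = 1, solver_config(1e-4))
  expect_lt(max(abs(sort(dec$mixing$angles) - c(15, 75))), 2)

  ## at lambda = lambda_max the sources vanish but the mixing is estimated
  dec0 <- decompose_sample(mix$rows[1, ], mix$rows[2, ], M = 2,
                           delta_theta = 1, solver_config(1))
  expect_true(all(dec0$sources$S == 0))
  expect_equal(sort(dec0$mixing$angles), sort(dec$mixing$angles))
})

test_that("source recovery is equivariant under feature permutation given the mixing", {
  set.seed(60)
  A <- random_unit_mixing(3)
  X <- matrix(rnorm(40), 2, 20)
  p <- sample(20)
  f1 <- ist_solve(A, X, solver_config(1e-4, max_iter = 5000, tol = 1e-12))
  f2 <- ist_solve(A, X[, p], solver_config(1e-4, max_iter = 5000, tol = 1e-12))
  expect_equal(f2$S, f1$S[, p], tolerance = 1e-8)
})

test_that("angle rule assigns disease/control components per reference role", {
  mk <- function(angles) {
    a <- angles * pi / 180
    structure(list(A = rbind(cos(a), sin(a)), angles = angles,
                   n_scps_used = 10L), class = "mixing_estimate")
  }
  src <- structure(list(S = rbind(1:4, 5:8, 9:12), objective = 0,
                        iterations_run = 1L), class = "source_estimate")
  sel <- select_components(mk(c(10, 45, 80)), src, "control")
  expect_equal(sel$disease_angle, 80)
  expect_equal(sel$control_angle, 10)
  expect_equal(sel$disease_component, c(9, 10, 11, 12))
  expect_equal(sel$control_component, c(1, 2, 3, 4))
  expect_equal(nrow(sel$neutral_components), 1L)
  expect_gt(sel$disease_angle, sel$control_angle)  # control-reference invariant

  sel_d <- select_components(mk(c(10, 45, 80)), src, "disease")
  expect_equal(sel_d$disease_angle, 10)
  expect_equal(sel_d$control_angle, 80)
  expect_lt(sel_d$disease_angle, sel_d$control_angle)

  src2 <- structure(list(S = rbind(1:4, 5:8), objective = 0,
                         iterations_run = 1L), class = "source_estimate")
  sel2 <- select_components(mk(c(30, 60)), src2, "control")
  expect_equal(sel2$disease_angle, 60)
  expect_equal(sel2$control_angle, 30)
  expect_equal(nrow(sel2$neutral_components), 0L)

  expect_warning(select_components(mk(c(50, 50)), src2, "control"), "tie")
})

test_that("selection agrees with the enumeration oracle on random matrices", {
  set.seed(61)
  for (rep in 1:200) {
    M <- sample(2:5, 1)
    angles <- round(runif(M, 0, 90), sample(c(0, 1, 3), 1))  # occasional ties
    a <- angles * pi / 180
    mixing <- structure(list(A = rbind(cos(a), sin(a)), angles = angles,
                             n_scps_used = 5L), class = "mixing_estimate")
    src <- structure(list(S = matrix(seq_len(2 * M), M, 2), objective = 0,
                          iterations_run = 1L), class = "source_estimate")
    for (role in c("control", "disease")) {
      oracle <- selection_oracle(angles, role)
      sel <- suppressWarnings(select_components(mixing, src, role))
      expect_equal(sel$disease_angle, angles[oracle$disease])
      expect_equal(sel$control_angle, angles[oracle$control])
      expect_equal(sel$disease_component, src$S[oracle$disease, ])
    }
  }
})

test_that("extraction yields four aligned labelled sets without using labels", {
  sim <- simulate_mixture(sim_config(K = 300, n_disease = 3, n_control = 3,
                                     seed = 6))
  cs <- extract_feature_sets(sim$dataset, M = 3, delta_theta = 5,
                             solver = solver_config(1e-4))
  expect_named(cs$sets, c("controlref_disease", "controlref_control",
                          "diseaseref_control", "diseaseref_disease"))
  for (s in cs$sets) expect_equal(dim(s), c(6L, 300L))
  expect_equal(cs$labels, sim$dataset$labels)
  ## control-reference extraction always has disease angle above control angle
  expect_true(all(cs$angles[, "controlref_disease"] >
                  cs$angles[, "controlref_control"]))
  expect_true(all(cs$angles[, "diseaseref_disease"] <
                  cs$angles[, "diseaseref_control"]))

  ## label non-use: decomposing the same mixture yields identical selected
  ## components whatever the labels say (selection reads only angles)
  ref <- build_reference(sim$dataset, -1)
  x <- sim$dataset$values[2, ]
  dec <- decompose_sample(ref, x, 3, 5, solver_config(1e-4))
  s1 <- select_components(dec$mixing, dec$sources, "control")
  s2 <- select_components(dec$mixing, dec$sources, "control")
  expect_identical(s1$disease_component, s2$disease_component)
})

test_that("train-only references ignore held-out samples", {
  sim <- simulate_mixture(sim_config(K = 300, n_disease = 4, n_control = 4,
                                     seed = 7))
  ds <- sim$dataset
  train <- ds$sample_ids[c(1, 2, 5, 6)]
  cs1 <- extract_feature_sets(ds, M = 2, delta_theta = 5,
                              solver = solver_config(1e-4),
                              reference_policy = "train_only",
                              train_ids = train)
  ## perturb a held-out sample: references must not move
  ds2 <- ds
  ds2$values[4, ] <- ds2$values[4, ] * 3 + 1
  cs2 <- extract_feature_sets(ds2, M = 2, delta_theta = 5,
                              solver = solver_config(1e-4),
                              reference_policy = "train_only",
                              train_ids = train)
  expect_identical(cs1$references, cs2$references)
  ## training-sample decompositions are unchanged too
  expect_identical(cs1$sets$controlref_disease[1, ],
                   cs2$sets$controlref_disease[1, ])
  expect_error(extract_feature_sets(ds, M = 2, delta_theta = 5,
                                    reference_policy = "train_only"),
               "train_ids")
})

test_that("per-sample failures are reported with the sample context", {
  ds <- expression_dataset(rbind(rep(1, 8), rep(2, 8), rep(3, 8), rep(4, 8)),
                           c(1, 1, -1, -1),
                           sample_ids = c("d1", "d2", "c1", "c2"))
  ## flat rows have a zero imaginary part: no SCPs anywhere
  expect_error(extract_feature_sets(ds, M = 2, delta_theta = 1),
               "sample d1")
})
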