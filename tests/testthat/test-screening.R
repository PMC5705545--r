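test_that("rank_database orders candidates by consensus score", {
  q <- bit_fp(0:9, "synth64")
  cons <- build_consensus("single", list(q = q))
  cands <- list(
    self = q,                          # Tanimoto 1
    near = bit_fp(0:8, "synth64"),     # 9/10
    far = bit_fp(c(0:4, 20:24), "synth64"), # 5/15
    mid = bit_fp(c(0:6, 30:32), "synth64")  # 7/13
  )
  ranked <- rank_database(cons, cands,
                          labels = c("active", "active", "inactive",
                                     "inactive"))
  expect_identical(ranked$mol_id, c("self", "near", "mid", "far"))
  expect_equal(ranked$score, c(1, 9 / 10, 7 / 13, 5 / 15))
  expect_identical(ranked$rank, 1:4)
  expect_error(rank_database(cons, list()), "candidate")
})

test_that("ties keep stable input order", {
  cons <- build_consensus("single", list(q = bit_fp(0:3, "synth64")))
  same <- bit_fp(0:1, "synth64")
  ranked <- rank_database(cons, list(first = same, second = same,
                                     third = same))
  expect_identical(ranked$mol_id, c("first", "second", "third"))
})

test_that("matrix fast path equals pairwise cscore for every policy", {
  set.seed(404)
  ds <- toy_dataset()
  acts <- ds$mol_id[ds$label == "active"]
  q_ids <- sample(acts, 4L)
  q_fps <- lapply(q_ids, consensr:::row_fp, dataset = ds)
  names(q_fps) <- q_ids
  pot <- potency_weights(data.frame(mol_id = q_ids,
                                    ic50 = ds$ic50[match(q_ids,
                                                         ds$mol_id)]))
  for (p in c("oppo", "pess", "opti", "real", "know")) {
    cons <- build_consensus(p, q_fps, if (p == "know") pot)
    ranked <- rank_database(cons, ds, subset = setdiff(ds$mol_id, q_ids))
    slow <- vapply(ranked$mol_id, function(id)
      cscore(cons, consensr:::row_fp(ds, id)), numeric(1))
    expect_equal(unname(ranked$score), unname(slow), tolerance = 1e-12)
  }
})

test_that("retrospective experiments are seed-deterministic and guarded", {
  ds <- toy_dataset()
  cfg <- experiment_config("oppo", csize = 3, repetitions = 6, seed = 31)
  r1 <- retrospective_experiment(ds, cfg)
  r2 <- retrospective_experiment(ds, cfg)
  expect_identical(r1$auc, r2$auc)
  expect_identical(r1$pm, r2$pm)
  expect_identical(r1$median_curve, r2$median_curve)
  expect_length(r1$auc, 6L)
  # query actives leave the screened database: curve covers |M| - N ranks
  expect_equal(nrow(r1$median_curve), length(ds$mol_id) - 3L)
  r3 <- retrospective_experiment(ds, experiment_config("oppo", csize = 3,
                                                       repetitions = 6,
                                                       seed = 99))
  expect_false(identical(r1$auc, r3$auc))
  expect_error(retrospective_experiment(
    ds, experiment_config("oppo", csize = 8, repetitions = 2, seed = 1)),
    "actives")
  expect_error(experiment_config("oppo", csize = 1), "2..20")
  expect_error(experiment_config("single", csize = 3), "csize = 1")
})

test_that("single-policy enumeration uses each active in turn", {
  ds <- toy_dataset(n_act = 5L)
  cfg_a <- experiment_config("single", csize = 1, repetitions = 5,
                             seed = 1, single_mode = "enumerate")
  cfg_b <- experiment_config("single", csize = 1, repetitions = 5,
                             seed = 777, single_mode = "enumerate")
  r_a <- retrospective_experiment(ds, cfg_a)
  r_b <- retrospective_experiment(ds, cfg_b)
  # enumeration is seed-free: one repetition per active, in order
  expect_identical(r_a$auc, r_b$auc)
})

test_that("CPU-bounded screens scale the slow policy's database", {
  ds <- toy_dataset()
  fast <- experiment_config("opti", csize = 3, repetitions = 4, seed = 3)
  slow <- experiment_config("oppo", csize = 3, repetitions = 4, seed = 3)
  n_cand <- length(ds$mol_id) - 3L
  out2 <- cpu_bounded_compare(ds, fast, slow, speedup = 2)
  expect_equal(nrow(out2$fast), n_cand)
  expect_equal(nrow(out2$slow), floor(n_cand / 2))
  out1 <- cpu_bounded_compare(ds, fast, slow, speedup = 1)
  expect_equal(nrow(out1$slow), n_cand)
  expect_error(cpu_bounded_compare(ds, fast, slow, speedup = 0.5),
               "speedup")
})

test_that("delta ranks are zero when a policy is compared to itself", {
  ds <- toy_dataset()
  dr <- delta_rank_analysis(ds, "real", "real", csize = 3,
                            repetitions = 4, seed = 5)
  expect_equal(nrow(dr), sum(ds$label == "active"))
  expect_true(all(dr$delta_rank == 0))
  # ordered by decreasing IC50 (least potent first)
  expect_true(all(diff(dr$ic50) <= 0))
  ds_noic <- ds
  ds_noic$ic50[ds_noic$label == "active"][1] <- NA
  expect_error(delta_rank_analysis(ds_noic, "know", "real", csize = 3,
                                   repetitions = 2, seed = 1), "IC50")
})

test_that("potency scaling pulls potent actives up the ranking", {
  # knowledgeable vs realist on a dataset with a wide potency spread:
  # the most potent actives should on balance move to better (lower) ranks
  ds <- generate_target(synth_config(n_actives = 20, n_inactives = 180,
                                     space_length = 128, n_modes = 2,
                                     density = 0.1, potency_range_logs = 4,
                                     seed = 15))
  dr <- delta_rank_analysis(ds, "know", "real", csize = 5,
                            repetitions = 30, seed = 15)
  top <- utils::tail(dr, 5) # most potent five (list is least-potent-first)
  bottom <- utils::head(dr, 5)
  expect_lte(mean(top$delta_rank), mean(bottom$delta_rank))
})
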