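test_that("visit filters remove exactly the configured rows", {
  cl <- claims_rows(
    list("p1", "a", 2004, "routine", "GP"),
    list("p2", "a", 2004, "emergency", "GP"),
    list("p3", "a", 2004, "emergency", "GP"),
    list("p4", "b", 2004, "emergency", "Radiology"),
    list("p5", "b", 2004, "routine", "Radiology"),
    list("p6", "c", 2004, "routine", "Anaesthesiology"),
    list("p7", "c", 2004, "routine", "Neuropathology"),
    list("p8", "d", 2004, "routine", "Surgery"),
    list("p9", "d", 2004, "routine", "UnknownSpecialty"),
    list("p9", "d", 2004, "routine", "GP")
  )
  out <- filter_claims(cl, filter_config())
  ## 3 emergency + 3 excluded-specialty routine rows drop; unknown labels stay
  expect_identical(nrow(out), 4L)
  expect_true(all(out$visit_type == "routine"))
  expect_true("UnknownSpecialty" %in% out$specialty)
  ## all rows of an excluded specialty -> empty
  rad <- cl[specialty == "Radiology"]
  expect_identical(nrow(filter_claims(rad, filter_config())), 0L)
  ## independent row-scan oracle on a random mixed table
  set.seed(42)
  vocab <- specialty_vocabulary()
  big <- data.table(
    patient_id = sample(sprintf("p%03d", 1:50), 400, TRUE),
    practice_id = sample(letters[1:8], 400, TRUE),
    year = sample(2004:2006, 400, TRUE),
    visit_type = sample(c("routine", "emergency"), 400, TRUE, c(0.8, 0.2)),
    specialty = sample(vocab, 400, TRUE))
  cfg <- filter_config()
  keep <- logical(400)
  for (i in 1:400) {
    keep[i] <- big$visit_type[i] != "emergency" &&
      !(big$specialty[i] %in% cfg$excluded_specialties)
  }
  expect_identical(filter_claims(big, cfg), big[keep])
  ## input untouched
  expect_identical(nrow(big), 400L)
})

test_that("activity rule counts distinct patients with a sharp boundary", {
  mk <- function(np, pr) {
    rbindlist(lapply(seq_len(np), function(i) {
      data.table(patient_id = sprintf("%s_p%d", pr, i), practice_id = pr,
                 year = 2004L, visit_type = "routine", specialty = "GP")
    }))
  }
  cl <- rbind(mk(30, "in30"), mk(29, "out29"))
  ## duplicated visits by one patient count once
  cl <- rbind(cl, cl[practice_id == "out29"][1:5])
  ids <- active_practices(cl, 2004, filter_config())
  expect_identical(ids, "in30")
  ## rule off -> everyone claiming
  expect_identical(active_practices(cl, 2004,
                                    filter_config(min_patients_per_year = 0)),
                   c("in30", "out29"))
  ## absent year -> empty
  expect_length(active_practices(cl, 2010, filter_config()), 0)
  ## distinct counting equals a set-based oracle
  set.seed(7)
  big <- data.table(patient_id = sample(sprintf("p%02d", 1:40), 500, TRUE),
                    practice_id = sample(letters[1:6], 500, TRUE),
                    year = 2004L)
  cfg <- filter_config(min_patients_per_year = 20)
  oracle <- sort(names(Filter(function(v) v >= 20, sapply(
    split(big$patient_id, big$practice_id),
    function(p) length(unique(p))))))
  expect_identical(active_practices(big, 2004, cfg), oracle)
})

test_that("shared-patient counting matches brute force and its invariants", {
  cl <- claims_rows(
    list("a", "x", 2004), list("b", "x", 2004), list("c", "x", 2004),
    list("a", "y", 2004), list("b", "y", 2004), list("c", "y", 2004),
    list("d", "z", 2004))
  m <- count_shared_patients(cl, 2004, c("x", "y", "z"))
  expect_identical(m$counts["x", "y"], 3L)
  expect_identical(m$counts["x", "z"], 0L)
  expect_identical(diag(m$counts), c(x = 0L, y = 0L, z = 0L))
  ## absent node id -> zero row/column
  m2 <- count_shared_patients(cl, 2004, c("x", "ghost"))
  expect_true(all(m2$counts["ghost", ] == 0L))
  ## random table equals the O(pairs x patients) double loop
  set.seed(13)
  big <- data.table(patient_id = sample(sprintf("p%02d", 1:30), 300, TRUE),
                    practice_id = sample(letters[1:7], 300, TRUE),
                    year = 2004L)
  ids <- letters[1:7]
  got <- count_shared_patients(big, 2004, ids)$counts
  expect_identical(got, bf_shared_counts(big, 2004, ids))
  expect_identical(got, t(got))
  ## a pair's count never exceeds either practice's patient pool
  sizes <- sapply(split(big$patient_id, big$practice_id),
                  function(p) length(unique(p)))
  for (i in 1:6) for (j in (i + 1):7) {
    expect_lte(got[i, j], min(sizes[ids[i]], sizes[ids[j]]))
  }
})

test_that("thresholding keeps exactly the qualifying pairs", {
  cl <- rbindlist(lapply(1:9, function(i) {
    data.table(patient_id = sprintf("s%d", i), practice_id = c("x", "y"),
               year = 2004L)
  }))
  cl8 <- rbindlist(lapply(1:8, function(i) {
    data.table(patient_id = sprintf("t%d", i), practice_id = c("x", "z"),
               year = 2004L)
  }))
  m <- count_shared_patients(rbind(cl, cl8), 2004, c("x", "y", "z"))
  net9 <- apply_threshold(m, 9L)
  ## 9 shared -> edge; 8 shared -> no edge; isolated node retained
  expect_identical(net9$edges[, .(node_a, node_b)],
                   data.table(node_a = "x", node_b = "y"))
  expect_identical(nrow(net9$nodes), 3L)
  net1 <- apply_threshold(m, 1L)
  expect_identical(nrow(net1$edges), 2L)
  expect_error(apply_threshold(m, 0L), ">= 1")
  ## elementwise oracle on a random matrix
  set.seed(3)
  big <- data.table(patient_id = sample(sprintf("p%02d", 1:40), 600, TRUE),
                    practice_id = sample(letters[1:8], 600, TRUE),
                    year = 2004L)
  mm <- count_shared_patients(big, 2004, letters[1:8])
  for (th in c(2L, 4L)) {
    net <- apply_threshold(mm, th)
    expected <- sum(mm$counts[upper.tri(mm$counts)] >= th)
    expect_identical(nrow(net$edges), expected)
    for (r in seq_len(nrow(net$edges))) {
      expect_gte(mm$counts[net$edges$node_a[r], net$edges$node_b[r]], th)
    }
  }
})

test_that("yearly construction composes the stages consistently", {
  b <- cached("tiny_bundle", simulate_claims(tiny_cfg(seed = 5L), seed = 5L))
  cfg <- filter_config()
  nets <- cached("tiny_nets",
                 build_networks(b$claims, b$practices, b$patients, cfg))
  expect_length(nets, 8L)
  kept <- filter_claims(b$claims, cfg)
  for (k in c(1L, 5L)) {
    net <- nets[[k]]
    expect_identical(net$nodes$practice_id,
                     active_practices(kept, net$year, cfg))
    expect_true(all(net$edges$shared_count >= cfg$shared_patient_threshold))
    expect_false(any(net$edges$node_a == net$edges$node_b))
  }
  ## node attributes: n_patients equals brute-force distinct count
  net <- nets[[3]]
  sub <- unique(kept[year == net$year, .(patient_id, practice_id)])
  for (pid in net$nodes$practice_id[1:5]) {
    expect_identical(net$nodes[practice_id == pid, n_patients],
                     nrow(sub[practice_id == pid]))
  }
})

test_that("edge sets shrink monotonically in the threshold", {
  b <- cached("tiny_bundle", simulate_claims(tiny_cfg(seed = 5L), seed = 5L))
  lad <- c(3L, 6L, 9L, 12L, 15L)
  edge_sets <- lapply(lad, function(th) {
    nets <- build_networks(b$claims, b$practices, b$patients,
                           filter_config(shared_patient_threshold = th))
    unlist(lapply(nets, function(n) {
      paste(n$year, n$edges$node_a, n$edges$node_b)
    }))
  })
  for (k in seq_len(length(lad) - 1)) {
    expect_true(all(edge_sets[[k + 1]] %in% edge_sets[[k]]))
  }
  ## strict shrinkage somewhere along the ladder
  expect_gt(length(edge_sets[[1]]), length(edge_sets[[5]]))
})

test_that("counting is row-order invariant and patient removal is monotone", {
  b <- cached("tiny_bundle", simulate_claims(tiny_cfg(seed = 5L), seed = 5L))
  cfg <- filter_config()
  nets <- cached("tiny_nets",
                 build_networks(b$claims, b$practices, b$patients, cfg))
  set.seed(99)
  shuffled <- b$claims[sample(.N)]
  nets2 <- build_networks(shuffled, b$practices, b$patients, cfg)
  for (k in seq_along(nets)) {
    expect_identical(nets[[k]]$edges, nets2[[k]]$edges)
  }
  ## removing one patient's claims can only remove or preserve edges
  victim <- b$claims$patient_id[1]
  nets3 <- build_networks(b$claims[patient_id != victim],
                          b$practices, b$patients, cfg)
  for (k in seq_along(nets)) {
    before <- paste(nets[[k]]$edges$node_a, nets[[k]]$edges$node_b)
    after <- paste(nets3[[k]]$edges$node_a, nets3[[k]]$edges$node_b)
    expect_true(all(after %in% before))
  }
})
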