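# Builds tiny RfSelectionResult / CorrelationNetwork objects directly so
# the intersection logic is exercised in isolation.

fake_rf <- function(selected, universe = paste0("OTU_", 1:6)) {
  ranks <- seq_along(selected)
  names(ranks) <- selected
  methods::new("RfSelectionResult",
               path = data.frame(n_otus = c(length(universe),
                                            length(selected)),
                                 oob_error = c(0.3, 0.1)),
               selected = selected,
               importanceRank = as.integer(ranks),
               params = list(otu_ids = universe))
}

fake_net <- function(edges, nodes) {
  r <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  p <- matrix(1, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  diag(r) <- 1
  diag(p) <- 0
  for (e in edges) {
    r[e[[1]], e[[2]]] <- r[e[[2]], e[[1]]] <- as.numeric(e[[3]])
    p[e[[1]], e[[2]]] <- p[e[[2]], e[[1]]] <- 1e-6
  }
  thresholdNetwork(r, p, r_threshold = 0.5, p_threshold = 0.001)
}

test_that("key OTUs are the intersection of the two selection routes", {
  nodes <- c(paste0("OTU_", 1:6), "storage_days")
  net <- fake_net(list(list("OTU_2", "storage_days", 0.7),
                       list("OTU_3", "OTU_4", 0.6),
                       list("OTU_4", "storage_days", -0.55)),
                  nodes)
  rf <- fake_rf(c("OTU_1", "OTU_2", "OTU_3"))
  keys <- intersectKeyOtus(rf, net)
  expect_setequal(keys$otu_id, c("OTU_2", "OTU_3"))
  expect_identical(keys$direction[keys$otu_id == "OTU_2"], "long")
  expect_true(all(keys$evidence == "rf,network"))
  # ordering: |r_storage| descending
  expect_identical(keys$otu_id[1], "OTU_2")

  # storage-edge-only mode drops the OTU-OTU-linked hit
  keys2 <- intersectKeyOtus(rf, net, storage_edge_only = TRUE)
  expect_identical(keys2$otu_id, "OTU_2")

  # pooled strata: union of selections, minimal rank, origins recorded
  rf_list <- list(T2 = fake_rf(c("OTU_2")), T6 = fake_rf(c("OTU_4")))
  keys3 <- intersectKeyOtus(rf_list, net)
  expect_setequal(keys3$otu_id, c("OTU_2", "OTU_4"))
  expect_identical(keys3$direction[keys3$otu_id == "OTU_4"], "short")
  expect_identical(keys3$origin[keys3$otu_id == "OTU_4"], "T6")
})

test_that("empty routes and disjoint universes are handled", {
  nodes <- c(paste0("OTU_", 1:6), "storage_days")
  net <- fake_net(list(list("OTU_2", "storage_days", 0.7)), nodes)
  # RF selected nothing that is connected
  keys <- intersectKeyOtus(fake_rf("OTU_5"), net)
  expect_identical(nrow(keys), 0L)
  # disjoint universes
  rf_bad <- fake_rf("X_1", universe = paste0("X_", 1:4))
  expect_error(intersectKeyOtus(rf_bad, net), "disjoint")
})

test_that("direction labels follow sign then class means", {
  expect_identical(assignDirection(0.7), "long")
  expect_identical(assignDirection(-0.6), "short")
  expect_identical(
    assignDirection(0, c(short = 0.001, medium = 0.004, long = 0.002)),
    "medium")
  expect_warning(dir <- assignDirection(0, c(short = 1, medium = 1,
                                             long = 1)), "unset")
  expect_true(is.na(dir))
})

test_that("direction labels swap when storage time is reversed", {
  withr::with_seed(91, {
    n <- 30
    days <- rep(seq(135, 169, length.out = 10), each = 3)
    X <- cbind(OTU_up = days + rnorm(n, sd = 3),
               OTU_dn = -days + rnorm(n, sd = 3),
               OTU_noise = rnorm(n))
    rf <- fake_rf(c("OTU_up", "OTU_dn"),
                  universe = colnames(X))
    keys_fwd <- intersectKeyOtus(
      rf, thresholdNetwork(spearmanMatrix(X, storage_days = days)))
    reflected <- max(days) + min(days) - days
    keys_rev <- intersectKeyOtus(
      rf, thresholdNetwork(spearmanMatrix(X, storage_days = reflected)))
    dir_fwd <- setNames(keys_fwd$direction, keys_fwd$otu_id)
    dir_rev <- setNames(keys_rev$direction, keys_rev$otu_id)
    expect_identical(dir_fwd[["OTU_up"]], "long")
    expect_identical(dir_rev[["OTU_up"]], "short")
    expect_identical(dir_fwd[["OTU_dn"]], "short")
    expect_identical(dir_rev[["OTU_dn"]], "long")
  })
})
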