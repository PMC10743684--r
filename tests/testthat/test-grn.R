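mk_grn <- function(label, tfs, targets) {
  e <- data.frame(tf = tfs, target = targets, stringsAsFactors = FALSE)
  structure(list(phenotype = label, edges = e,
                 tf_set = sort(unique(e$tf)),
                 target_set = sort(unique(e$target))),
            class = "regulatory_network")
}

test_that("topology counts match set arithmetic, including the empty network", {
  empty <- mk_grn("e", character(), character())
  expect_equal(grn_topology(empty),
               list(n_nodes = 0L, n_links = 0L, n_targets = 0L, n_tfs = 0L))
  g <- mk_grn("x", c("TF1", "TF1", "TF2"), c("A", "B", "B"))
  expect_equal(grn_topology(g),
               list(n_nodes = 4L, n_links = 3L, n_targets = 2L, n_tfs = 2L))

  set.seed(17)
  for (rep in 1:20) {
    tfs <- sample(sprintf("TF%d", 1:5), 15, replace = TRUE)
    tgs <- sample(sprintf("G%d", 1:10), 15, replace = TRUE)
    e <- unique(data.frame(tf = tfs, target = tgs))
    g <- mk_grn("r", e$tf, e$target)
    topo <- grn_topology(g)
    expect_equal(topo$n_links, nrow(e))
    expect_equal(topo$n_nodes, length(unique(c(e$tf, e$target))))
    expect_equal(topo$n_tfs, length(unique(e$tf)))
    expect_equal(topo$n_targets, length(unique(e$target)))
  }
})

test_that("target-count distributions report per-TF out-degree", {
  g <- mk_grn("x", c(rep("T1", 1), rep("T2", 2), rep("T3", 3), rep("T4", 4)),
              sprintf("G%d", 1:10))
  d <- target_count_distribution(list(x = g))$x
  expect_equal(d$summary$mean, 2.5)
  expect_equal(d$counts$n_targets[d$counts$tf == "T3"], 3L)
  e <- target_count_distribution(list(e = mk_grn("e", character(), character())))$e
  expect_equal(nrow(e$counts), 0L)
})

test_that("set intersections partition the union exactly", {
  a <- mk_grn("a", c("T1", "T2"), c("G1", "G2"))
  b <- mk_grn("b", c("T1", "T2"), c("G3", "G4"))
  same <- set_intersections(list(a = a, b = b), what = "tf")
  expect_equal(unname(same$regions["a&b"]), 2L)
  expect_equal(same$shared_by_all, 2L)
  disj <- set_intersections(list(a = a, b = b), what = "target")
  expect_equal(sort(names(disj$regions)), c("a", "b"))
  expect_equal(disj$shared_by_all, 0L)

  set.seed(18)
  uni <- sprintf("E%02d", 1:50)
  grns <- lapply(1:5, function(i)
    mk_grn(paste0("p", i), paste0("T", i), "G1"))
  names(grns) <- paste0("p", 1:5)
  for (i in 1:5) {
    s <- sample(uni, sample(5:30, 1))
    grns[[i]]$target_set <- sort(s)
  }
  res <- set_intersections(grns, what = "target")
  expect_equal(sum(res$regions),
               length(unique(unlist(lapply(grns, `[[`, "target_set")))))
  # every region count matches direct enumeration
  for (region in names(res$regions)) {
    labs <- strsplit(region, "&", fixed = TRUE)[[1]]
    inside <- Reduce(intersect, lapply(grns[labs], `[[`, "target_set"))
    outside <- unique(unlist(lapply(grns[setdiff(names(grns), labs)],
                                    `[[`, "target_set")))
    expect_equal(unname(res$regions[region]), length(setdiff(inside, outside)))
  }
  names(grns)[2] <- "p1"
  expect_error(set_intersections(grns), class = "coexloc_usage_error")
})

test_that("regulators per target equal transpose degrees with chromosome labels", {
  ann <- data.frame(gene_id = c("G1", "G2", "G3"),
                    chromosome = c("1", "17", "17"))
  g <- mk_grn("x", c("T1", "T2", "T1", "T3"), c("G1", "G1", "G2", "G3"))
  r <- regulators_per_target(g, ann)
  expect_equal(r$per_target$in_degree[r$per_target$target == "G1"], 2L)
  expect_equal(r$per_target$chromosome[r$per_target$target == "G2"], "17")
  expect_identical(r$chromosome_coverage, c("1", "17"))
  # degrees equal an independent tabulation of the edge list transpose
  tab <- table(g$edges$target)
  expect_equal(setNames(r$per_target$in_degree, r$per_target$target)[names(tab)],
               setNames(as.integer(tab), names(tab)))
})

test_that("unique-TF subnetworks equal direct set differences", {
  ann <- data.frame(gene_id = sprintf("G%d", 1:6),
                    chromosome = c("17", "17", "17", "1", "2", "3"))
  a <- mk_grn("a", c("SHARED", "UA", "UA"), c("G1", "G2", "G3"))
  b <- mk_grn("b", c("SHARED", "UB"), c("G1", "G4"))
  u <- unique_tf_subnetworks(list(a = a, b = b), ann)
  expect_identical(u$a$unique_tfs, "UA")
  expect_identical(u$b$unique_tfs, "UB")
  # SHARED is excluded everywhere
  expect_false("SHARED" %in% c(u$a$unique_tfs, u$b$unique_tfs))
  # UA's targets all on chromosome 17 -> purity flag
  expect_true(u$a$per_tf$UA$single_chromosome)

  set.seed(19)
  for (rep in 1:10) {
    sets <- lapply(1:3, function(i) sample(sprintf("T%d", 1:8), sample(2:6, 1)))
    grns <- lapply(1:3, function(i) mk_grn(paste0("p", i), sets[[i]],
                                           rep("G1", length(sets[[i]]))))
    names(grns) <- paste0("p", 1:3)
    u <- unique_tf_subnetworks(grns, ann)
    for (i in 1:3) {
      want <- setdiff(sets[[i]], unlist(sets[-i]))
      expect_setequal(u[[i]]$unique_tfs, want)
    }
  }
})

test_that("star structures are found exactly by the degree definition", {
  ann <- data.frame(gene_id = sprintf("G%d", 1:20),
                    chromosome = rep(c("1", "2"), each = 10))
  # star: hub TF with 6 exclusive targets
  star <- mk_grn("s", rep("HUB", 6), sprintf("G%d", 1:6))
  s <- star_structures(star, min_leaves = 3L, ann = ann)
  expect_length(s, 1L)
  expect_identical(s[[1]]$center, "HUB")
  expect_length(s[[1]]$leaves, 6L)
  expect_true(s[[1]]$single_chromosome)   # G1-G6 all lie on chromosome 1

  # densely shared targets: every target in-degree >= 2 -> no stars
  dense <- mk_grn("d", c("T1", "T2", "T1", "T2"), c("G1", "G1", "G2", "G2"))
  expect_length(star_structures(dense, min_leaves = 2L), 0L)

  expect_error(star_structures(star, min_leaves = 1L),
               class = "coexloc_usage_error")

  # planted stars among noise, versus a brute-force degree scan
  e_tf <- c(rep("S1", 4), rep("S2", 3), "N1", "N2", "N1")
  e_tg <- c(sprintf("G%d", 1:4), sprintf("G%d", 11:13), "G15", "G15", "G16")
  g <- mk_grn("m", e_tf, e_tg)
  found <- star_structures(g, min_leaves = 3L, ann = ann)
  centers <- vapply(found, `[[`, "", "center")
  expect_setequal(centers, c("S1", "S2"))
  s1 <- found[[which(centers == "S1")]]
  expect_true(s1$single_chromosome)       # G1-G4 all on chromosome 1
  s2 <- found[[which(centers == "S2")]]
  expect_true(s2$single_chromosome)       # G11-G13 all on chromosome 2
})
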