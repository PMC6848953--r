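test_that("the shipped dictionary recomputes masses from formulas", {
  tr <- default_transformations()
  expect_gte(nrow(tr), 40L)
  expect_true(all(tr$delta_mass > 0))
  expect_equal(tr$delta_mass, monoisotopic_mass(tr$formula),
               tolerance = 1e-12)
  expect_equal(tr$delta_mass[tr$name == "CO2"], 43.989829, tolerance = 1e-6)
  expect_equal(tr$delta_mass[tr$name == "CH2"], 14.015650, tolerance = 1e-6)
})

test_that("transformation files are validated row-wise", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,formula,delta_mass",
               "CO2,CO2,",
               "CH2,CH2,14.01565",
               "bad_pair,CO2,44.5",     # inconsistent mass/formula
               "no_mass,,",             # neither formula nor mass
               "custom,,100.123"),      # mass-only row is fine
             f)
  expect_warning(tr <- read_transformations(f), "2 transformation row")
  expect_identical(tr$name, c("CO2", "CH2", "custom"))
  expect_equal(tr$delta_mass[1], 43.98983, tolerance = 1e-5)
  # empty dictionary means an edgeless network
  g <- withr::local_tempfile(fileext = ".csv")
  writeLines("name,formula,delta_mass", g)
  expect_identical(nrow(build_network(c(100, 143.98983),
                                      read_transformations(g))$edges), 0L)
})

test_that("edges appear exactly at transformation mass differences", {
  co2 <- default_transformations()
  co2 <- co2[co2$name == "CO2", ]
  net <- build_network(c(100.0, 143.98983), co2, tol_da = 0.001)
  expect_identical(nrow(net$edges), 1L)
  expect_identical(net$edges$transformation, "CO2")
  expect_lt(abs(net$edges$residual_da), 1e-5)
  # CH2 ladder forms a two-edge path
  ch2 <- default_transformations()
  ch2 <- ch2[ch2$name == "CH2", ]
  path <- build_network(c(100, 114.01565, 128.03130), ch2)
  expect_identical(nrow(path$edges), 2L)
  # beyond tolerance: nothing
  far <- build_network(c(100, 143.992), co2, tol_da = 0.001)
  expect_identical(nrow(far$edges), 0L)
})

test_that("the sorted-scan edge finder matches the all-pairs oracle", {
  set.seed(17)
  tr <- default_transformations()
  tr <- tr[tr$name %in% c("CH2", "CO2", "H2O", "O", "C6H10O5"), ]
  mz <- sort(runif(150, 100, 900))
  # salt in true transformation partners so edges exist
  mz <- sort(c(mz, mz[1:25] + sample(tr$delta_mass, 25, replace = TRUE)))
  net <- build_network(mz, tr, tol_da = 0.001)
  oracle <- all_pairs_edges(mz, tr, 0.001)
  expect_identical(nrow(net$edges), nrow(oracle))
  expect_equal(net$edges$low_mz, oracle$low_mz)
  expect_equal(net$edges$high_mz, oracle$high_mz)
  expect_identical(net$edges$transformation, oracle$transformation)
  # permutation invariance
  net2 <- build_network(rev(mz), tr, tol_da = 0.001)
  expect_identical(net2$edges, net$edges)
  # every edge residual honors the tolerance
  expect_true(all(abs(net$edges$residual_da) <= 0.001))
})

test_that("first neighbors induce the seed-adjacent subnetwork", {
  tr <- default_transformations()
  tr <- tr[tr$name %in% c("CH2", "CO2"), ]
  seed <- 400
  partners <- seed + c(tr$delta_mass, -tr$delta_mass, 2 * 43.98983)
  net <- build_network(c(seed, partners, 800), tr)
  fn <- first_neighbors(net, seed)
  expect_identical(fn$n_neighbors, 4L)   # the double-CO2 and 800 are not adjacent
  expect_true(seed %in% fn$nodes$mz)
  # a seed with no edges is returned alone
  lone <- first_neighbors(net, 800)
  expect_identical(lone$n_neighbors, 0L)
  expect_identical(nrow(lone$nodes), 1L)
  # two seeds sharing a neighbor count it once
  two <- first_neighbors(net, c(seed, seed + 43.98983))
  expect_lte(two$n_neighbors,
             length(unique(c(fn$nodes$mz, seed + 2 * 43.98983))))
  # unmatched seeds are skipped with a message
  expect_message(first_neighbors(net, 123.456), "not present")
})

test_that("annotation attaches formulas and classes, unknown otherwise", {
  mz <- c(mz_from_neutral(monoisotopic_mass("C18H34O2")), 500.123)
  net <- build_network(mz, default_transformations())
  a <- data.frame(mz = mz[1], formula = "C18H34O2")
  ann <- annotate_network(net, a)
  expect_identical(ann$nodes$class[ann$nodes$mz == mz[1]], "lipid")
  expect_identical(ann$nodes$class[ann$nodes$mz == mz[2]], "unknown")
  tally <- class_tally(ann)
  expect_identical(sum(tally), nrow(ann$nodes))
})

test_that("planted chains are recovered with high precision and recall", {
  spec <- synthetic_spec(seed = 19, n_compounds = 150, jitter_ppm = 0.05,
                         chains = list(n = 5, length = 5,
                                       transformations = c("CO2", "H2O",
                                                           "CH2", "O")))
  s <- generate_sample(spec)
  net <- build_network(s$peaks$mz, tol_da = 0.001)
  # planted edges: consecutive chain members
  tr <- default_transformations()
  planted <- 0L; found <- 0L
  for (cid in unique(na.omit(s$truth$chain_id))) {
    members <- s$truth[which(s$truth$chain_id == cid), ]
    members <- members[order(members$true_mz), ]
    if (nrow(members) < 2L) next
    for (i in seq_len(nrow(members) - 1L)) {
      planted <- planted + 1L
      hit <- any(abs(net$edges$low_mz - members$mz[i]) < 1e-9 &
                   abs(net$edges$high_mz - members$mz[i + 1]) < 1e-9)
      found <- found + as.integer(hit)
    }
  }
  expect_gte(planted, 10L)
  expect_gte(found / planted, 0.95)
})

test_that("networks serialize to GraphML and CSV", {
  dir <- withr::local_tempdir()
  net <- build_network(c(100, 143.98983, 157.988),
                       default_transformations())
  net <- annotate_network(net, data.frame(mz = 100, formula = "C6H12O6"))
  paths <- write_network(net, file.path(dir, "net"))
  expect_true(all(file.exists(paths)))
  g <- as_igraph(net)
  expect_equal(igraph::vcount(g), nrow(net$nodes), ignore_attr = TRUE)
  expect_equal(igraph::ecount(g), nrow(net$edges), ignore_attr = TRUE)
})
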