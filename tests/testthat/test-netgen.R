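test_that("degree sequences respect the truncated support and parity", {
  set.seed(101)
  for (case in list(list(n = 200, lam = 2.2), list(n = 1000, lam = 1.5),
                    list(n = 5000, lam = 2.2))) {
    deg <- sample_degree_sequence(case$n, case$lam)
    expect_length(deg, case$n)
    expect_gte(min(deg), 2L)
    expect_lte(max(deg), floor(sqrt(case$n)))
    expect_identical(sum(deg) %% 2L, 0L)
  }
  # an extreme exponent collapses all mass onto the minimum degree
  deg <- sample_degree_sequence(100, 50)
  expect_true(all(deg == 2L))
  expect_error(sample_degree_sequence(3, 2.2), "integer")
  expect_error(sample_degree_sequence(100, 0.5), "> 1")
})

test_that("degree frequencies match the analytic truncated law", {
  set.seed(202)
  n <- 5000; lam <- 2.2; kmax <- floor(sqrt(n))
  # independent oracle: direct normalization of k^-lambda
  z <- sum((2:kmax)^(-lam))
  p2 <- 2^(-lam) / z
  p3 <- 3^(-lam) / z
  reps <- 60
  f2 <- f3 <- numeric(reps)
  for (r in seq_len(reps)) {
    deg <- sample_degree_sequence(n, lam)
    f2[r] <- mean(deg == 2L)
    f3[r] <- mean(deg == 3L)
  }
  expect_lt(abs(mean(f2) - p2), 3 * sd(f2) / sqrt(reps) + 1e-12)
  expect_lt(abs(mean(f3) - p3), 3 * sd(f3) / sqrt(reps) + 1e-12)
  # and the packaged pmf agrees with the direct sum
  expect_equal(degree_pmf(c(2, 3), lam, 2, kmax), c(p2, p3))
})

test_that("stub matching preserves degrees exactly and yields simple graphs", {
  # [2,2,2] admits a unique simple graph: the triangle
  g <- build_graph(c(2L, 2L, 2L))
  expect_identical(g$degree, c(2L, 2L, 2L))
  expect_setequal(neighbors(g, 1), c(2L, 3L))

  set.seed(303)
  for (r in 1:5) {
    deg <- sample_degree_sequence(400, 2.2)
    g <- build_graph(deg)
    expect_identical(g$degree, deg)
    src <- rep.int(seq_len(g$n), g$degree)
    expect_true(all(src != g$nbr))              # no self loops
    key <- pmin(src, g$nbr) * (g$n + 1) + pmax(src, g$nbr)
    expect_identical(anyDuplicated(key[src < g$nbr]), 0L)  # no parallel edges
    # symmetry: each undirected edge appears once in each direction
    expect_identical(sort(key[src < g$nbr]), sort(key[src > g$nbr]))
  }
  expect_error(build_graph(c(2L, 2L)), "n - 1")
  expect_error(build_graph(c(1L, 1L, 1L)), "even")
})

test_that("built graphs reproduce the truncated power-law CDF", {
  set.seed(404)
  g <- generate_network(5000, 2.2)
  kmax <- floor(sqrt(5000))
  z <- sum((2:kmax)^(-2.2))
  cdf_target <- cumsum((2:kmax)^(-2.2) / z)
  cdf_emp <- vapply(2:kmax, function(k) mean(g$degree <= k), numeric(1))
  # KS-type distance; 1.36/sqrt(n) ~ 0.019 is the 5% null band for n = 5000
  expect_lt(max(abs(cdf_emp - cdf_target)), 0.03)
})

test_that("population assignment pins the hard core and draws the majority", {
  set.seed(505)
  g <- generate_network(2000, 2.2)
  pop <- assign_population(g, 3)
  hc <- pop[pop$is_hc, ]
  mj <- pop[!pop$is_hc, ]
  expect_true(all(hc$degree == 3L))
  expect_true(all(hc$b == -1L) && all(hc$sigma == 1))
  expect_true(all(mj$b == 1L))
  expect_true(all(mj$sigma > 0 & mj$sigma <= 1))
  expect_true(all(pop$omega == 0L) && !any(pop$has_expressed))
  expect_equal(hc_prevalence(pop), mean(g$degree == 3L))

  tri <- build_graph(c(2L, 2L, 2L))
  expect_error(assign_population(tri, 5), class = "quietnet_empty_hard_core")

  # trivial prevalence values
  pop5 <- assign_population(g, 5)
  pop5$is_hc <- FALSE
  expect_equal(hc_prevalence(pop5), 0)
})

test_that("hard-core prevalence decreases with the hard-core degree", {
  set.seed(606)
  kcs <- c(2L, 3L, 5L, 10L)
  prev <- sapply(kcs, function(kc) {
    mean(replicate(20, {
      g <- generate_network(2000, 2.2)
      mean(g$degree == kc)
    }))
  })
  expect_true(all(diff(prev) < 0))
})

test_that("edge-list and population files round-trip with the stated formats", {
  set.seed(707)
  g <- generate_network(300, 2.2)
  path <- withr::local_tempfile(fileext = ".txt")
  write_edgelist(g, path)
  first <- strsplit(readLines(path, n = 1), " ")[[1]]
  expect_length(first, 2)                      # two 0-based ids per line
  g2 <- read_edgelist(path, n_nodes = g$n)
  expect_identical(g2$degree, g$degree)
  expect_identical(g2$nbr, g$nbr)

  pop <- assign_population(g, 3)
  pcsv <- withr::local_tempfile(fileext = ".csv")
  write_population(pop, pcsv)
  expect_identical(readLines(pcsv, n = 1), "node,degree,b,sigma,is_hc")
})

test_that("identical seeds reproduce the network and population exactly", {
  make <- function(seed) {
    set.seed(seed)
    g <- generate_network(500, 2.2)
    list(g = g, pop = assign_population(g, 3))
  }
  a <- make(11); b <- make(11); c <- make(12)
  expect_identical(a$g, b$g)
  expect_identical(a$pop, b$pop)
  expect_false(identical(a$g$nbr, c$g$nbr))
})
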