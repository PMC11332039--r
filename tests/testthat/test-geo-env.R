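test_that("FST linearization is elementwise x/(1-x) and rejects FST = 1", {
  m <- matrix(c(0, 0.2, 0.5, 0.2, 0, 0, 0.5, 0, 0), 3)
  lin <- linearize_fst(m)
  expect_equal(lin[1, 2], 0.25)
  expect_equal(lin[1, 3], 1.0)
  expect_equal(lin[2, 3], 0)
  expect_error(linearize_fst(matrix(c(0, 1, 1, 0), 2)), "infinite")
})

test_that("great-circle distances hit analytic anchors and wrap longitude", {
  co <- data.frame(lon = c(0, 90, 0), lat = c(0, 0, 0))
  rownames(co) <- c("o", "e", "o2")
  m <- great_circle_km(co)
  expect_equal(m["o", "o2"], 0)
  expect_equal(m["o", "e"], 6371 * pi / 2, tolerance = 1e-6)
  co2 <- data.frame(lon = c(170, -170 + 360), lat = c(10, 10))
  co3 <- data.frame(lon = c(170, -170), lat = c(10, 10))
  expect_equal(great_circle_km(co2)[1, 2], great_circle_km(co3)[1, 2])
  expect_error(great_circle_km(data.frame(lon = 0, lat = 95)), "coordinates")
})

test_that("island coordinates average their site coordinates", {
  sim <- fixture_sim()
  ic <- island_coordinates(sim$meta)
  expect_equal(nrow(ic), 11)
  i1 <- sim$meta[sim$meta$island == "I01", ]
  expect_equal(ic["I01", "lat"], mean(i1$lat))
})

test_that("environment PCA distance retains the right number of components", {
  # five duplicated copies of one descriptor -> a single PC carries all
  # variance
  set.seed(8)
  base <- rnorm(10)
  env <- data.frame(site_id = paste0("s", 1:10),
                    a = base, b = 2 * base + 1, c = -base, d = base / 3,
                    e = base + 5)
  dm <- env_pca_distance(env)
  expect_equal(attr(dm, "n_pcs"), 1)
  # two identical sites -> distance 0
  env2 <- env
  env2[2, -1] <- env2[1, -1]
  dm2 <- env_pca_distance(env2)
  expect_equal(unname(dm2["s1", "s2"]), 0)
  # constant column dropped with warning
  env3 <- cbind(env, konst = 1)
  expect_warning(env_pca_distance(env3), "constant")
})

test_that("the synthetic descriptor table reduces to the latent gradient", {
  sim <- fixture_sim()
  dm <- env_pca_distance(sim$env, level = "island")
  expect_lte(attr(dm, "n_pcs"), 5)
  scores <- attr(dm, "scores")
  r <- cor(scores[, 1], sim$truth$island_gradient)
  expect_gt(abs(r), 0.9)
})

test_that("mantel on identical matrices gives r = 1 and the minimal p", {
  set.seed(2)
  x <- as.matrix(dist(matrix(rnorm(24), 12)))
  dimnames(x) <- list(paste0("i", 1:12), paste0("i", 1:12))
  mt <- mantel_test(x, x, n_perm = 999, seed = 7)
  expect_equal(mt$r, 1)
  expect_equal(mt$p, 1 / 1000)
})

test_that("mantel is invariant to affine rescaling and joint relabeling", {
  set.seed(4)
  x <- as.matrix(dist(matrix(rnorm(20), 10)))
  y <- as.matrix(dist(matrix(rnorm(20), 10)))
  labs <- paste0("i", 1:10)
  dimnames(x) <- dimnames(y) <- list(labs, labs)
  m1 <- mantel_test(x, y, n_perm = 499, seed = 3)
  m2 <- mantel_test(x, 10 * y + 2, n_perm = 499, seed = 3)
  expect_equal(m1$r, m2$r)
  expect_equal(m1$p, m2$p)
  perm <- sample(10)
  m3 <- mantel_test(x[perm, perm], y[perm, perm], n_perm = 499, seed = 3)
  expect_equal(m3$r, m1$r)
  expect_error(mantel_test(x[1:3, 1:3], y[1:3, 1:3]), "at least 4")
  expect_error(mantel_test(x * 0, y), "zero-variance")
})

test_that("isolation by distance is detected when built in and not when shuffled", {
  # genetic distance constructed to decay with island geographic distance
  sim <- fixture_sim()
  geo <- great_circle_km(island_coordinates(sim$meta))
  set.seed(12)
  gen <- geo / max(geo) + matrix(rnorm(length(geo), 0, 0.1), nrow(geo))
  gen <- (gen + t(gen)) / 2
  diag(gen) <- 0
  dimnames(gen) <- dimnames(geo)
  mt <- mantel_test(gen, geo, n_perm = 999, seed = 5)
  expect_lt(mt$p, 0.01)
  shuf <- sample(nrow(geo))
  geo_shuffled <- geo[shuf, shuf]
  dimnames(geo_shuffled) <- dimnames(geo)
  mt0 <- mantel_test(gen, geo_shuffled, n_perm = 999, seed = 5)
  expect_gt(mt0$p, 0.05)
})
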