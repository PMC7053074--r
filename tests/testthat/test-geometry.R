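# perfect unit honeycomb spanning the periodic strip: width 10, rows at
# sqrt(3)/2 spacing, so every interior Voronoi region is a regular hexagon
honeycomb_pop <- function() {
  rows <- 12
  dy <- sqrt(3) / 2
  ij <- expand.grid(i = 0:9, j = seq_len(rows) - 1)
  pop <- initialize_crypt(mechanics_config(), model = "vl", seed = 1)
  pop$x <- (ij$i + 0.5 * (ij$j %% 2)) %% 10
  pop$y <- ij$j * dy + 0.2
  pop$n <- nrow(ij)
  for (f in c("id", "gamma", "age", "G1", "duration", "proliferative",
              "differentiated", "drag"))
    pop[[f]] <- rep(pop[[f]][1], pop$n)
  pop$id <- seq_len(pop$n)
  pop$partner <- rep(NA_integer_, pop$n)
  pop$states <- pop$states[rep(1, pop$n), , drop = FALSE]
  pop
}

test_that("interior honeycomb cells have 6 neighbours and hexagon areas", {
  pop <- honeycomb_pop()
  tess <- crypt_tessellation(pop)
  deg <- tabulate(c(tess$edges), pop$n)
  interior <- pop$y > 1.5 & pop$y < max(pop$y) - 1.5
  expect_true(all(deg[interior] == 6))
  expect_equal(tess$areas[interior], rep(sqrt(3) / 2, sum(interior)),
               tolerance = 1e-9)
})

test_that("tessellation areas partition the crypt rectangle", {
  pop <- initialize_crypt(mechanics_config(), model = "vl", seed = 2)
  expect_equal(sum(voronoi_areas(pop)), 200, tolerance = 1e-9)
  expect_equal(sum(voronoi_areas(initialize_crypt(small_mechanics(),
                                                  model = "vl", seed = 2))),
               50, tolerance = 1e-9)
})

test_that("periodic wraparound connects cells across the seam", {
  pop <- honeycomb_pop()
  pop$x[1] <- 0.1
  pop$y[1] <- 5
  pop$x[2] <- 9.9
  pop$y[2] <- 5
  edges <- neighbours(pop)
  hit <- any((edges[, 1] == 1 & edges[, 2] == 2))
  expect_true(hit)
  d <- multicrypt:::.displacement(pop, 1L, 2L)
  expect_equal(as.numeric(d), c(-0.2, 0))
})

test_that("edges beyond the neighbour cutoff are discarded", {
  pop <- honeycomb_pop()
  # isolate a pair 3 CD apart high above the lattice
  pop$x[1] <- 2
  pop$y[1] <- 18
  pop$x[2] <- 5
  pop$y[2] <- 18
  edges <- neighbours(pop)
  expect_false(any(edges[, 1] == 1 & edges[, 2] == 2))
})

test_that("neighbour sets match the deldir oracle on ghosted points", {
  skip_if_not_installed("deldir")
  set.seed(31)
  pop <- initialize_crypt(mechanics_config(), model = "vl", seed = 31)
  pop$x <- (pop$x + runif(pop$n, -0.3, 0.3)) %% 10
  pop$y <- pmax(pop$y + runif(pop$n, -0.3, 0.3), 0)
  tess <- crypt_tessellation(pop)

  # oracle: plain Delaunay on the strip plus ghost copies shifted +-10
  gx <- c(pop$x, pop$x + 10, pop$x - 10)
  gy <- rep(pop$y, 3)
  dd <- deldir::deldir(gx, gy)
  ind <- ((dd$delsgs$ind1 - 1) %% pop$n) + 1
  ind2 <- ((dd$delsgs$ind2 - 1) %% pop$n) + 1
  dx <- abs(pop$x[ind] - pop$x[ind2])
  dx <- pmin(dx, 10 - dx)
  len <- sqrt(dx^2 + (pop$y[ind] - pop$y[ind2])^2)
  keep <- ind != ind2 & len <= 1.5
  oracle <- unique(t(apply(cbind(ind, ind2)[keep, ], 1, sort)))
  oracle <- oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE]
  mine <- tess$edges[order(tess$edges[, 1], tess$edges[, 2]), , drop = FALSE]
  expect_equal(unname(mine), unname(oracle))
})

test_that("areas match the deldir tile oracle away from the seam", {
  skip_if_not_installed("deldir")
  set.seed(32)
  pop <- initialize_crypt(mechanics_config(), model = "vl", seed = 32)
  pop$x <- (pop$x + runif(pop$n, -0.3, 0.3)) %% 10
  pop$y <- pmax(pop$y + runif(pop$n, -0.3, 0.3), 0)
  areas <- voronoi_areas(pop)
  gx <- c(pop$x, pop$x + 10, pop$x - 10)
  gy <- rep(pop$y, 3)
  tiles <- deldir::tile.list(deldir::deldir(gx, gy, rw = c(-10, 20, 0, 20)))
  # compare cells whose tiles cannot touch the ghost boundary
  inner <- which(pop$x > 2 & pop$x < 8 & pop$y > 2 & pop$y < 18)
  oracle <- unname(vapply(tiles[inner], function(t) t$area, 0))
  expect_equal(areas[inner], oracle, tolerance = 1e-5) # deldir rounds areas
})

test_that("spring forces follow the linear law with maturing rest lengths", {
  pop <- honeycomb_pop()
  pop$x[1] <- 3
  pop$y[1] <- 17
  pop$x[2] <- 4
  pop$y[2] <- 17
  expect_equal(pairwise_force(1, 2, pop), c(0, 0)) # at rest length

  pop$x[2] <- 4.2
  f <- pairwise_force(1, 2, pop)
  expect_equal(f, c(0.2 * pop$mu, 0)) # overstretched: attractive, mu * 0.2

  # newborn sibling pair at age 0.5 h: rest length 0.1 + 0.9 * 0.5 = 0.55
  pop$partner[1] <- pop$id[2]
  pop$partner[2] <- pop$id[1]
  pop$age[1] <- pop$age[2] <- 0.5
  pop$x[2] <- 3.55
  expect_equal(pairwise_force(1, 2, pop), c(0, 0))

  expect_error({
    pop$x[2] <- pop$x[1]
    pop$y[2] <- pop$y[1]
    pairwise_force(1, 2, pop)
  }, "coincident")
})

test_that("forces are equal and opposite and translation invariant", {
  set.seed(5)
  pop <- initialize_crypt(mechanics_config(), model = "vl", seed = 5)
  pop$x <- (pop$x + runif(pop$n, -0.2, 0.2)) %% 10
  pop$y <- pmax(pop$y + runif(pop$n, -0.2, 0.2), 0)
  tess <- crypt_tessellation(pop)
  F <- multicrypt:::.net_forces(pop, tess$edges)
  expect_lt(max(abs(colSums(F))), 1e-9)

  shifted <- pop
  shifted$x <- (pop$x + 3.7) %% 10
  tess2 <- crypt_tessellation(shifted)
  F2 <- multicrypt:::.net_forces(shifted, tess2$edges)
  expect_equal(voronoi_areas(shifted), voronoi_areas(pop), tolerance = 1e-8)
  expect_equal(F2, F, tolerance = 1e-8)
})

test_that("position update scales with drag, wraps x and clamps the base", {
  pop <- honeycomb_pop()
  F <- matrix(0, pop$n, 2)
  expect_equal(step_positions(pop, F)$x, pop$x)

  F[1, ] <- c(12, 0)
  F[2, ] <- c(12, 0)
  pop$drag[1] <- 1
  pop$drag[2] <- 20
  out <- step_positions(pop, F, dt = 0.01)
  d1 <- (out$x[1] - pop$x[1]) %% 10
  d2 <- (out$x[2] - pop$x[2]) %% 10
  expect_equal(d1 / d2, 20)

  pop2 <- honeycomb_pop()
  pop2$y[1] <- 0.02
  F2 <- matrix(0, pop2$n, 2)
  F2[1, 2] <- -10
  out2 <- step_positions(pop2, F2, dt = 0.05)
  expect_equal(out2$y[1], 0) # pushed into the base: clamped

  F3 <- matrix(0, pop$n, 2)
  F3[5, 1] <- 1e6
  expect_error(step_positions(honeycomb_pop(), F3, dt = 1), "1 cell diameter")
})

test_that("sloughing removes exactly the cells at or above the crypt top", {
  pop <- initialize_crypt(mechanics_config(), model = "vl", seed = 3)
  pop$y[1] <- 20.01
  pop$y[2] <- 19.99
  pop$y[3] <- 20
  out <- slough(pop)
  expect_equal(out$n, pop$n - 2)
  expect_false(any(out$id %in% pop$id[c(1, 3)]))
  expect_true(pop$id[2] %in% out$id)
  # no-op when nothing is above the top
  expect_equal(slough(out)$n, out$n)
})
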