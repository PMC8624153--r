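test_that("von Neumann neighbours wrap periodically and are symmetric", {
  nb <- vonNeumannNeighbors(c(0, 0), 25)
  expect_equal(nrow(unique(nb)), 4L)
  expect_setequal(apply(nb, 1, paste, collapse = ","),
                  c("24,0", "1,0", "0,24", "0,1"))
  expect_error(vonNeumannNeighbors(c(0, 0), 2), "degenerate")
  # symmetry of the neighbour relation on random sites
  set.seed(42)
  for (k in 1:20) {
    s <- c(sample(0:6, 1), sample(0:6, 1))
    nb <- vonNeumannNeighbors(s, 7)
    for (r in seq_len(4)) {
      back <- vonNeumannNeighbors(nb[r, ], 7)
      expect_true(any(back[, 1] == s[1] & back[, 2] == s[2]))
    }
  }
})

test_that("random configurations respect counts and seeds", {
  cfg <- randomConfig(25, nTypes = 3, seed = 11)
  expect_equal(typeCounts(cfg), c(209L, 208L, 208L))
  expect_identical(latticeTypes(randomConfig(25, nTypes = 3, seed = 11)),
                   latticeTypes(cfg))
  expect_false(identical(latticeTypes(randomConfig(25, nTypes = 3, seed = 12)),
                         latticeTypes(cfg)))
  expect_error(randomConfig(5, counts = c(10, 10)), "sum to side\\^2")
})

test_that("reference patterns have the expected contact structure", {
  # stripes: fully phase separated, two interface rows on the torus
  s <- referenceConfig("stripes", 26, 2)
  expect_equal(totalHomotypic(s), 2 * 26^2 - 2 * 26)
  # chessboard on even side: no homotypic contacts
  cb <- referenceConfig("chessboard", 26, 2)
  expect_equal(totalHomotypic(cb), 0L)
  # diagonal stripes with side divisible by N: all-heterotypic for N = 3
  dg <- referenceConfig("diagonal_stripes", 24, 3)
  expect_equal(totalHomotypic(dg), 0L)
  # odd-side chessboard is allowed but flagged
  expect_warning(cb25 <- referenceConfig("chessboard", 25, 2), "wrap defects")
  expect_true(attr(cb25, "flagged"))
  expect_equal(totalHomotypic(cb25), 50L)  # one defect line per dimension
})

test_that("applySwitch is an involution that conserves counts", {
  cfg <- randomConfig(6, nTypes = 2, seed = 5)
  tm <- latticeTypes(cfg)
  # find an adjacent heterotypic pair
  x <- NULL
  for (r in 0:5) for (c in 0:5) {
    if (tm[r + 1, c + 1] != tm[r + 1, (c + 1) %% 6 + 1]) {
      x <- c(r, c); y <- c(r, (c + 1) %% 6); break
    }
  }
  swapped <- applySwitch(cfg, x, y)
  expect_equal(typeCounts(swapped), typeCounts(cfg))
  expect_identical(latticeTypes(applySwitch(swapped, x, y)),
                   latticeTypes(cfg))
  # only x and y changed
  diff <- latticeTypes(swapped) != latticeTypes(cfg)
  expect_equal(sum(diff), 2L)
  # homotypic pair and non-adjacent pair are contract violations
  hom <- NULL
  for (r in 0:5) for (c in 0:5) {
    if (tm[r + 1, c + 1] == tm[r + 1, (c + 1) %% 6 + 1]) {
      hom <- list(c(r, c), c(r, (c + 1) %% 6)); break
    }
  }
  expect_error(applySwitch(cfg, hom[[1]], hom[[2]]), "homotypic")
  expect_error(applySwitch(cfg, c(0, 0), c(2, 0)), "not adjacent")
})

test_that("switch changes the contact count only through the local edges", {
  set.seed(8)
  for (k in 1:10) {
    cfg <- randomConfig(5, nTypes = 3, seed = k)
    tab <- buildEventTable(cfg, adhesionParams(rep(0, 6)))
    row <- tab[sample(nrow(tab), 1), ]
    x <- c(row$x_row, row$x_col); y <- c(row$y_row, row$y_col)
    after <- applySwitch(cfg, x, y)
    # local delta: only edges incident to N(x) u N(y) u {x,y} may change
    dFull <- totalHomotypic(after) - totalHomotypic(cfg)
    local <- function(cf) {
      tm <- latticeTypes(cf)
      cnt <- 0L
      for (s in list(x, y)) {
        for (r in seq_len(4)) {
          nb <- vonNeumannNeighbors(s, 5)[r, ]
          if (tm[s[1] + 1, s[2] + 1] == tm[nb[1] + 1, nb[2] + 1])
            cnt <- cnt + 1L
        }
      }
      cnt
    }
    # the (x,y) edge is heterotypic before and after; it is counted from
    # both endpoints in neither case, so the difference of the local sums
    # equals the global difference
    expect_equal(local(after) - local(cfg), dFull)
  }
})

test_that("configurations serialize to grid text and JSON and back", {
  cfg <- randomConfig(7, nTypes = 3, seed = 3)
  grid <- tempfile(fileext = ".txt")
  js <- tempfile(fileext = ".json")
  writeLatticeConfig(cfg, grid)
  writeLatticeConfig(cfg, js, seed = 3)
  expect_identical(latticeTypes(readLatticeConfig(grid)), latticeTypes(cfg))
  back <- readLatticeConfig(js)
  expect_identical(latticeTypes(back), latticeTypes(cfg))
  expect_equal(typeCounts(back), typeCounts(cfg))
})
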