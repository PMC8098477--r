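test_that("P212121 operators match the reference table", {
  sg <- space_group("P 21 21 21")
  expect_identical(sg$symbol, "P212121")
  expect_identical(sg_n_ops(sg), 4L)
  ## oracle: gemmi triplets x,y,z / -x+1/2,-y,z+1/2 / x+1/2,-y+1/2,-z /
  ## -x,y+1/2,-z+1/2
  triplet <- function(op) {
    ax <- c("x", "y", "z")
    paste(vapply(1:3, function(i) {
      term <- ""
      for (j in 1:3) {
        cf <- op$R[i, j]
        if (cf == 1) term <- paste0(term, if (nzchar(term)) "+" else "", ax[j])
        if (cf == -1) term <- paste0(term, "-", ax[j])
      }
      if (op$t[i] == 0.5) term <- paste0(term, "+1/2")
      term
    }, character(1)), collapse = ",")
  }
  got <- vapply(sg$ops, triplet, character(1))
  expect_setequal(got, c("x,y,z", "-x+1/2,-y,z+1/2", "x+1/2,-y+1/2,-z",
                         "-x,y+1/2,-z+1/2"))
})

test_that("operators of every group form a closed set", {
  for (sym in c("P1", "P2", "P21", "P222", "P212121", "P4", "P41", "P43",
                "P41212", "P43212")) {
    sg <- space_group(sym)
    keyify <- function(R, t) paste(c(round(R, 9), round(t %% 1, 9)),
                                   collapse = ",")
    keys <- vapply(sg$ops, function(o) keyify(o$R, o$t), character(1))
    for (a in sg$ops) for (b in sg$ops) {
      R <- a$R %*% b$R
      t <- as.vector(a$R %*% b$t) + a$t
      expect_true(keyify(R, t) %in% keys, label = paste(sym, "closure"))
    }
  }
})

test_that("centric classification and allowed phases match gemmi", {
  hkl <- rbind(c(1, 2, 0), c(0, 2, 3), c(1, 0, 3), c(1, 2, 3), c(3, 0, 0),
               c(0, 1, 1))
  ci <- centric_info(hkl, "P212121")
  ## oracle: gemmi; theta values modulo 180 (allowed pair theta, theta+180)
  expect_identical(ci$centric, c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(ci$theta[c(1, 2, 3, 5, 6)] %% 180, c(90, 0, 90, 90, 90),
               tolerance = 1e-9)
  expect_true(is.na(ci$theta[4]))
  ci2 <- centric_info(rbind(c(1, 1, 0), c(1, -1, 0), c(0, 0, 4), c(1, 2, 3)),
                      "P41212")
  expect_identical(ci2$centric, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(ci2$theta[1:3] %% 180, c(0, 0, 0), tolerance = 1e-9)
})

test_that("permissible origins of P212121 are the eight half-cell points", {
  po <- permissible_origins("P212121")
  expect_identical(po$free, c(FALSE, FALSE, FALSE))
  expect_identical(nrow(po$points), 8L)
  g <- as.matrix(expand.grid(c(0, .5), c(0, .5), c(0, .5)))
  expect_equal(sort(apply(po$points, 1, paste, collapse = ",")),
               sort(apply(g, 1, paste, collapse = ",")))
})

test_that("polar axes are free origin components", {
  po <- permissible_origins("P21")   # unique axis b: y is polar
  expect_identical(po$free, c(FALSE, TRUE, FALSE))
  expect_identical(permissible_origins("P1")$free, c(TRUE, TRUE, TRUE))
  ## free components do not contribute to the distance
  expect_equal(origin_set_distance(c(0, 0.3, 0), "P21"), 0)
  expect_equal(origin_set_distance(c(0.25, 0.3, 0), "P21"), 0.25)
})

test_that("origin_set_distance uses the minimal image over the origin set", {
  expect_equal(origin_set_distance(c(0, 0, 0), "P212121"), 0)
  expect_equal(origin_set_distance(c(0.5, 0.5, 0.5), "P212121"), 0)
  expect_equal(origin_set_distance(c(0.98, 0.02, 0.52), "P212121"),
               sqrt(0.02^2 + 0.02^2 + 0.02^2), tolerance = 1e-12)
  expect_equal(origin_set_distance(c(0.25, 0, 0), "P212121"), 0.25)
})

test_that("asu_map picks one representative per orbit, reachable by the stored op", {
  sg <- space_group("P212121")
  hkl <- enumerate_hkl(study_cell(), 6)
  am <- asu_map(hkl, sg)
  for (i in seq_len(nrow(hkl))) {
    ## rep = sign * h %*% R[op]
    got <- am$sign[i] * as.vector(hkl[i, ] %*% sg$ops[[am$op[i]]]$R)
    expect_identical(as.integer(got), as.vector(am$rep[i, ]))
  }
  ## orbit members share a representative
  h <- c(2, 3, 4)
  orbit <- do.call(rbind, lapply(sg$ops, function(op) {
    he <- as.integer(h %*% op$R)
    rbind(he, -he)
  }))
  reps <- asu_map(orbit, sg)$rep
  expect_identical(nrow(unique(reps)), 1L)
})

test_that("sym_equivalents carries the phase-transport term", {
  eq <- sym_equivalents(c(1, 2, 3), "P212121")
  expect_length(eq, 4)
  ## op -x+1/2,-y,z+1/2: dphi = -360 (h.t) = -360*(0.5 + 1.5) = -720 -> 0
  expect_equal(eq[[2]]$dphi, 0)
  ## op -x,y+1/2,-z+1/2: t=(0,.5,.5), h.t = 1 + 1.5 = 2.5 -> -900 -> 180
  i <- which(vapply(eq, function(d) d$h == -1 && d$k == 2 && d$l == -3,
                    logical(1)))
  expect_equal(abs(eq[[i]]$dphi), 180)
})

test_that("unsupported symbols error", {
  expect_error(space_group("C2"), "unsupported")
  expect_error(space_group("P63"), "unsupported")
})
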