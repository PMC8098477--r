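## Minimal space-group engine: symmetry operators x' = R x + t acting on
## fractional coordinates. Reflection indices transform as row vectors,
## h_s = h R, with the phase relation phi(h R) = phi(h) - 360 * (h . t).

sg_op <- function(R, t) list(R = matrix(as.numeric(R), 3, 3), t = as.numeric(t))

## operator tables (general positions, standard settings)
.sg_table <- function() {
  I3 <- diag(3)
  ops <- list()
  ops[["P1"]] <- list(sg_op(I3, c(0, 0, 0)))
  ops[["P2"]] <- list(  # unique axis b
    sg_op(I3, c(0, 0, 0)),
    sg_op(diag(c(-1, 1, -1)), c(0, 0, 0)))
  ops[["P21"]] <- list(  # unique axis b
    sg_op(I3, c(0, 0, 0)),
    sg_op(diag(c(-1, 1, -1)), c(0, 0.5, 0)))
  ops[["P222"]] <- list(
    sg_op(I3, c(0, 0, 0)),
    sg_op(diag(c(-1, -1, 1)), c(0, 0, 0)),
    sg_op(diag(c(-1, 1, -1)), c(0, 0, 0)),
    sg_op(diag(c(1, -1, -1)), c(0, 0, 0)))
  ops[["P212121"]] <- list(
    sg_op(I3, c(0, 0, 0)),
    sg_op(diag(c(-1, -1, 1)), c(0.5, 0, 0.5)),
    sg_op(diag(c(-1, 1, -1)), c(0, 0.5, 0.5)),
    sg_op(diag(c(1, -1, -1)), c(0.5, 0.5, 0)))
  rot4p <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)  # -y,x,z
  rot4m <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)  # y,-x,z
  ops[["P4"]] <- list(
    sg_op(I3, c(0, 0, 0)),
    sg_op(diag(c(-1, -1, 1)), c(0, 0, 0)),
    sg_op(rot4p, c(0, 0, 0)),
    sg_op(rot4m, c(0, 0, 0)))
  ops[["P41"]] <- list(
    sg_op(I3, c(0, 0, 0)),
    sg_op(diag(c(-1, -1, 1)), c(0, 0, 0.5)),
    sg_op(rot4p, c(0, 0, 0.25)),
    sg_op(rot4m, c(0, 0, 0.75)))
  ops[["P43"]] <- list(
    sg_op(I3, c(0, 0, 0)),
    sg_op(diag(c(-1, -1, 1)), c(0, 0, 0.5)),
    sg_op(rot4p, c(0, 0, 0.75)),
    sg_op(rot4m, c(0, 0, 0.25)))
  dyx  <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, -1), 3, 3, byrow = TRUE)   # y,x,-z
  dmyx <- matrix(c(0, -1, 0, -1, 0, 0, 0, 0, -1), 3, 3, byrow = TRUE) # -y,-x,-z
  ops[["P41212"]] <- list(
    sg_op(I3, c(0, 0, 0)),
    sg_op(diag(c(-1, -1, 1)), c(0, 0, 0.5)),
    sg_op(rot4p, c(0.5, 0.5, 0.25)),
    sg_op(rot4m, c(0.5, 0.5, 0.75)),
    sg_op(diag(c(-1, 1, -1)), c(0.5, 0.5, 0.25)),
    sg_op(diag(c(1, -1, -1)), c(0.5, 0.5, 0.75)),
    sg_op(dyx, c(0, 0, 0)),
    sg_op(dmyx, c(0, 0, 0.5)))
  ops[["P43212"]] <- list(
    sg_op(I3, c(0, 0, 0)),
    sg_op(diag(c(-1, -1, 1)), c(0, 0, 0.5)),
    sg_op(rot4p, c(0.5, 0.5, 0.75)),
    sg_op(rot4m, c(0.5, 0.5, 0.25)),
    sg_op(diag(c(-1, 1, -1)), c(0.5, 0.5, 0.75)),
    sg_op(diag(c(1, -1, -1)), c(0.5, 0.5, 0.25)),
    sg_op(dyx, c(0, 0, 0)),
    sg_op(dmyx, c(0, 0, 0.5)))
  ops
}

normalize_sg_symbol <- function(symbol) {
  s <- gsub("[ _()]", "", symbol)
  sub <- c("P1" = "P1", "P2" = "P2", "P21" = "P21", "P222" = "P222",
           "P212121" = "P212121", "P4" = "P4", "P41" = "P41", "P43" = "P43",
           "P41212" = "P41212", "P43212" = "P43212")
  if (!s %in% names(sub)) stop("unsupported space group symbol: ", symbol)
  sub[[s]]
}

#' Space group
#'
#' Construct a space-group object carrying its symmetry operators (rotation
#' part `R`, fractional translation `t`, acting on coordinates as
#' `x' = R x + t`). Supported symbols: P1, P2, P21, P222, P212121, P4, P41,
#' P43, P41212, P43212.
#'
#' @param symbol Hermann-Mauguin symbol (spaces/underscores ignored).
#' @return an object of class `space_group` with elements `symbol` and `ops`.
#' @export
space_group <- function(symbol) {
  if (inherits(symbol, "space_group")) return(symbol)
  sym <- normalize_sg_symbol(symbol)
  structure(list(symbol = sym, ops = .sg_table()[[sym]]), class = "space_group")
}

#' @export
print.space_group <- function(x, ...) {
  cat(sprintf("space group %s (%d symmetry operators)\n", x$symbol, length(x$ops)))
  invisible(x)
}

#' Number of symmetry operators
#' @param sg a `space_group` or symbol.
#' @return integer count of operators.
#' @export
sg_n_ops <- function(sg) length(space_group(sg)$ops)

#' Symmetry-equivalent Miller indices
#'
#' Returns, for each input reflection, the equivalents `h R_s` for every
#' operator, together with the phase-transport term `-360 * (h . t_s)`.
#'
#' @param hkl integer matrix (n x 3).
#' @param sg a `space_group` or symbol.
#' @return list of data frames, one per operator, with columns h,k,l,dphi.
#' @export
sym_equivalents <- function(hkl, sg) {
  sg <- space_group(sg)
  hkl <- rbind(hkl)
  lapply(sg$ops, function(op) {
    he <- hkl %*% op$R
    data.frame(h = he[, 1], k = he[, 2], l = he[, 3],
               dphi = wrap_deg(-360 * as.vector(hkl %*% op$t)))
  })
}

#' Centric reflection test and allowed phases
#'
#' A reflection h is centric when some operator satisfies h R = -h; its phase
#' is then restricted to `180 * (h . t)` modulo 180 degrees.
#'
#' @param hkl integer matrix (n x 3).
#' @param sg a `space_group` or symbol.
#' @return data frame with logical `centric` and `theta` (one allowed phase in
#'   degrees; the other is `theta + 180`), NA where acentric.
#' @export
centric_info <- function(hkl, sg) {
  sg <- space_group(sg)
  hkl <- rbind(hkl)
  n <- nrow(hkl)
  centric <- rep(FALSE, n)
  theta <- rep(NA_real_, n)
  for (op in sg$ops) {
    he <- hkl %*% op$R
    hit <- !centric & rowSums(abs(he + hkl)) == 0
    if (any(hit)) {
      centric[hit] <- TRUE
      theta[hit] <- wrap_deg(180 * as.vector(hkl[hit, , drop = FALSE] %*% op$t))
    }
  }
  data.frame(centric = centric, theta = theta)
}

#' Permissible (equivalent) crystallographic origins
#'
#' Origin shifts v that leave the space-group operators unchanged satisfy
#' `(R_s - I) v` integral for every operator. Components unconstrained by any
#' operator (polar axes) are flagged free.
#'
#' @param sg a `space_group` or symbol.
#' @return list with `points` (matrix of fractional origins, free components
#'   set to 0) and `free` (logical 3-vector of polar axes).
#' @export
permissible_origins <- function(sg) {
  sg <- space_group(sg)
  M <- do.call(rbind, lapply(sg$ops, function(op) op$R - diag(3)))
  free <- colSums(abs(M)) < 1e-9
  vals <- seq(0, 0.75, by = 0.25)
  g <- as.matrix(expand.grid(x = vals, y = vals, z = vals))
  g[, free] <- 0
  g <- unique(g)
  ok <- apply(g, 1, function(v) {
    r <- M %*% v
    all(abs(r - round(r)) < 1e-9)
  })
  list(points = g[ok, , drop = FALSE], free = free)
}

#' Distance to the nearest permissible origin
#'
#' Minimal-image Euclidean distance (in fractional coordinates) from `u` to
#' the closest member of the space group's permissible-origin set; free (polar)
#' components do not contribute.
#'
#' @param u fractional 3-vector.
#' @param sg a `space_group` or symbol.
#' @return numeric scalar.
#' @export
origin_set_distance <- function(u, sg) {
  po <- permissible_origins(sg)
  d <- apply(po$points, 1, function(v) {
    dd <- (u - v) - round(u - v)
    dd[po$free] <- 0
    sqrt(sum(dd^2))
  })
  min(d)
}

## canonical ASU representative under the space group plus Friedel symmetry:
## the lexicographically largest member (by h, then k, then l) of the orbit
## {+/- h R_s}. Returns representative indices, the operator index and the
## Friedel sign used to reach the observed index from the representative.
asu_map <- function(hkl, sg) {
  sg <- space_group(sg)
  hkl <- rbind(hkl)
  n <- nrow(hkl)
  nop <- length(sg$ops)
  cand <- array(0, c(n, 3, 2 * nop))
  for (s in seq_len(nop)) {
    he <- hkl %*% sg$ops[[s]]$R
    cand[, , s] <- he
    cand[, , nop + s] <- -he
  }
  ## pick lexicographically largest (h, then k, then l) orbit member;
  ## scan candidates keeping a running best
  rep_idx <- matrix(cand[, , 1], n, 3)
  op_used <- rep(1L, n); sign_used <- rep(1L, n)
  for (j in seq_len(2 * nop)[-1]) {
    cj <- matrix(cand[, , j], n, 3)
    better <- (cj[, 1] > rep_idx[, 1]) |
      (cj[, 1] == rep_idx[, 1] & cj[, 2] > rep_idx[, 2]) |
      (cj[, 1] == rep_idx[, 1] & cj[, 2] == rep_idx[, 2] & cj[, 3] > rep_idx[, 3])
    if (any(better)) {
      rep_idx[better, ] <- cj[better, , drop = FALSE]
      op_used[better] <- ifelse(j > nop, j - nop, j)
      sign_used[better] <- ifelse(j > nop, -1L, 1L)
    }
  }
  ## rep = sign * h %*% R[op]  =>  observed h relates to rep via that op/sign
  storage.mode(rep_idx) <- "integer"
  list(rep = rep_idx, op = op_used, sign = sign_used)
}
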