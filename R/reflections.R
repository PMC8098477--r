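#' Reflection set
#'
#' A table of unique Miller indices with intensities, phases (degrees),
#' multiplicities and the tilt angle at which each reflection was recorded,
#' together with the unit cell and space group.
#'
#' @param hkl integer matrix (n x 3) of Miller indices.
#' @param I non-negative intensities.
#' @param phase phases in degrees (wrapped to (-180, 180]).
#' @param cell a `unit_cell`.
#' @param sg a `space_group` or symbol.
#' @param mult multiplicities (observation counts), default 1.
#' @param tilt recording tilt angle in degrees per reflection (NA if unknown).
#' @return an object of class `reflection_set`.
#' @export
reflection_set <- function(hkl, I, phase, cell, sg, mult = 1, tilt = NA_real_) {
  hkl <- rbind(hkl)
  storage.mode(hkl) <- "integer"
  n <- nrow(hkl)
  stopifnot(length(I) == n, length(phase) == n)
  if (any(I < 0)) stop("intensities must be non-negative")
  key <- hkl_key(hkl)
  if (anyDuplicated(key)) stop("duplicate Miller indices in reflection set")
  dimnames(hkl) <- list(NULL, c("h", "k", "l"))
  structure(list(hkl = hkl,
                 I = as.numeric(I),
                 phase = wrap_deg(as.numeric(phase)),
                 mult = rep_len(as.numeric(mult), n),
                 tilt = rep_len(as.numeric(tilt), n),
                 cell = cell,
                 sg = space_group(sg)),
            class = "reflection_set")
}

hkl_key <- function(hkl) paste(hkl[, 1], hkl[, 2], hkl[, 3])

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("reflection set: %d reflections, space group %s\n",
              nrow(x$hkl), x$sg$symbol))
  print(x$cell)
  invisible(x)
}

#' @export
summary.reflection_set <- function(object, d_min = NULL, ...) {
  q <- hkl_q(object$hkl, object$cell)
  cat(sprintf("%d reflections, d range %.2f - %.2f A, space group %s\n",
              nrow(object$hkl), 1 / min(q), 1 / max(q), object$sg$symbol))
  if (!is.null(d_min))
    cat(sprintf("P1 completeness to %.2f A: %.3f\n", d_min,
                completeness(object, d_min)))
  invisible(object)
}

#' Number of reflections
#' @param rs a `reflection_set`.
#' @return integer count.
#' @export
n_reflections <- function(rs) nrow(rs$hkl)

#' Subset a reflection set by row index
#' @param rs a `reflection_set`.
#' @param idx integer or logical row index.
#' @return a `reflection_set`.
#' @export
rs_subset <- function(rs, idx) {
  reflection_set(rs$hkl[idx, , drop = FALSE], rs$I[idx], rs$phase[idx],
                 rs$cell, rs$sg, rs$mult[idx], rs$tilt[idx])
}

#' Match shared reflections between two sets
#' @param a,b `reflection_set` objects.
#' @return data frame with row indices `ia`, `ib` of shared reflections.
#' @export
rs_match <- function(a, b) {
  ib <- match(hkl_key(a$hkl), hkl_key(b$hkl))
  ia <- which(!is.na(ib))
  data.frame(ia = ia, ib = ib[ia])
}

## ---------------------------------------------------------------------------
## pseudo-structures and structure factors

#' Generate a random pseudo-structure
#'
#' Places `n_atoms` Gaussian scatterers uniformly in the unit cell and expands
#' them by the space-group operators (wrapping into the cell), yielding an
#' atomic model that obeys the symmetry exactly. Used as a download-free
#' stand-in for real coordinate files in simulations and tests.
#'
#' @param seed RNG seed (integer).
#' @param n_atoms number of atoms in the asymmetric unit.
#' @param cell a `unit_cell`.
#' @param sg a `space_group` or symbol.
#' @return data frame with fractional coordinates `x`,`y`,`z`, scattering
#'   weight `w` and real-space Gaussian width `sigma` (Angstrom); attribute
#'   `asu_size` gives the number of symmetry-independent atoms.
#' @export
generate_pseudo_structure <- function(seed, n_atoms, cell, sg) {
  stopifnot(n_atoms >= 1)
  sg <- space_group(sg)
  rng <- local({
    set.seed(seed)
    list(x = matrix(runif(3 * n_atoms), n_atoms, 3),
         w = runif(n_atoms, 6, 14),
         s = runif(n_atoms, 0.8, 1.5))
  })
  model <- expand_atoms(data.frame(x = rng$x[, 1], y = rng$x[, 2], z = rng$x[, 3],
                                   w = rng$w, sigma = rng$s), sg)
  attr(model, "asu_size") <- n_atoms
  attr(model, "cell") <- cell
  attr(model, "sg") <- sg
  model
}

#' Expand an atomic model by space-group symmetry
#'
#' @param model data frame with fractional `x`,`y`,`z` (plus extra columns).
#' @param sg a `space_group` or symbol.
#' @return data frame with one row per atom per operator, coordinates wrapped
#'   into [0, 1).
#' @export
expand_atoms <- function(model, sg) {
  sg <- space_group(sg)
  out <- lapply(sg$ops, function(op) {
    xyz <- as.matrix(model[, c("x", "y", "z")]) %*% t(op$R)
    xyz <- sweep(xyz, 2, op$t, "+") %% 1
    m <- model
    m$x <- xyz[, 1]; m$y <- xyz[, 2]; m$z <- xyz[, 3]
    m
  })
  do.call(rbind, out)
}

#' Structure factors by direct summation
#'
#' Computes F(h) = sum_j w_j exp(-2 pi^2 sigma_j^2 q^2) exp(2 pi i h . x_j)
#' over the (symmetry-expanded) atoms of a Gaussian-scatterer model, for all
#' Friedel-unique reflections to `d_min`.
#'
#' @param model atomic model data frame (fractional x,y,z, weight w, width
#'   sigma); typically from [generate_pseudo_structure()].
#' @param cell a `unit_cell`.
#' @param sg a `space_group` or symbol (carried on the output set).
#' @param d_min high-resolution limit in Angstrom.
#' @param hkl optional explicit Miller index matrix instead of enumeration.
#' @return a `reflection_set` with I = |F|^2 and phase = arg F in degrees.
#' @export
structure_factors <- function(model, cell, sg, d_min, hkl = NULL) {
  if (is.null(hkl)) hkl <- enumerate_hkl(cell, d_min)
  Fc <- calc_structure_factor(model, cell, hkl)
  reflection_set(hkl, Mod(Fc)^2, Arg(Fc) * 180 / pi, cell, sg)
}

#' Complex structure factors for arbitrary Miller indices
#'
#' Direct-summation evaluation of F(h) for a Gaussian-scatterer model; unlike
#' [structure_factors()] the input indices need not be unique.
#'
#' @inheritParams structure_factors
#' @param hkl integer matrix (n x 3).
#' @return complex vector of structure factors.
#' @export
calc_structure_factor <- function(model, cell, hkl) {
  hkl <- rbind(hkl)
  q <- hkl_q(hkl, cell)
  X <- as.matrix(model[, c("x", "y", "z")])
  ph <- 2 * pi * (hkl %*% t(X))                    # n_hkl x n_atoms
  ff <- exp(-2 * pi^2 * outer(q^2, model$sigma^2)) # form factors
  as.vector((cos(ph) * ff) %*% model$w + 1i * ((sin(ph) * ff) %*% model$w))
}

## ---------------------------------------------------------------------------
## plain-text reflection table IO

#' Write a reflection set as a plain-text table
#'
#' Format: comment header lines carrying the cell and space group, then one
#' row per reflection `h k l I phase mult tilt`.
#'
#' @param rs a `reflection_set`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_reflections <- function(rs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# cell %.6f %.6f %.6f %.6f %.6f %.6f",
            rs$cell$a, rs$cell$b, rs$cell$c, rs$cell$alpha, rs$cell$beta,
            rs$cell$gamma),
    sprintf("# sg %s", rs$sg$symbol),
    "# h k l I phase mult tilt"), con)
  df <- data.frame(rs$hkl, I = rs$I, phase = rs$phase, mult = rs$mult,
                   tilt = rs$tilt)
  utils::write.table(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a reflection set written by [write_reflections()]
#'
#' @param path input file path.
#' @return a `reflection_set`.
#' @export
read_reflections <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  cl <- grep("^# cell ", hdr, value = TRUE)
  sl <- grep("^# sg ", hdr, value = TRUE)
  if (length(cl) != 1 || length(sl) != 1)
    stop("malformed reflection file header: need '# cell' and '# sg' lines")
  cp <- as.numeric(strsplit(sub("^# cell ", "", cl), "\\s+")[[1]])
  if (length(cp) != 6 || any(!is.finite(cp)))
    stop("malformed header field: cell")
  sg <- sub("^# sg ", "", sl)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  cell <- unit_cell(cp[1], cp[2], cp[3], cp[4], cp[5], cp[6])
  if (length(body) == 0)
    return(reflection_set(matrix(integer(0), 0, 3), numeric(0), numeric(0),
                          cell, sg))
  parts <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(parts, length, 1L) != 7)
  if (length(bad))
    stop("malformed reflection row at line ",
         which(!grepl("^#", lines))[bad[1]])
  m <- suppressWarnings(matrix(as.numeric(unlist(parts)), ncol = 7,
                               byrow = TRUE))  # NA allowed in tilt column only
  if (any(!is.finite(m[, 1:6])))
    stop("malformed reflection row: non-numeric field")
  reflection_set(m[, 1:3], m[, 4], m[, 5], cell, sg, m[, 6], m[, 7])
}
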