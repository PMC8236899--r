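#' @title Rigid-body domain superposition
#' @description
#' Least-squares rigid superposition (Kabsch algorithm, SVD form, reflections
#' excluded) of CA atoms matched through the canonical numbering: because the
#' hand-curated alignment already states which residues correspond across
#' structures, correspondences come from shared canonical positions rather
#' than from a sequence-independent structural aligner. This is what supports
#' the cross-structure comparisons of domain orientation (e.g. the large ib
#' domain orientation differences between pMHC-I and pMHC-II).
#' @name superposition
NULL

#' Kabsch least-squares fit
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD of
#' `mobile %*% t(R) + t` against `reference`.
#'
#' @param mobile,reference n x 3 coordinate matrices, equal `n >= 3`.
#' @return list with `R` (3 x 3, det +1), `t` (length 3) and `rmsd`
#'   (Angstrom).
#' @export
kabsch_fit <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)))
    stop("mobile and reference must have identical dimensions")
  n <- nrow(mobile)
  if (n < 3) stop("need at least 3 points to fit")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  if (svd(P)$d[2] < 1e-8 || svd(Q)$d[2] < 1e-8)
    stop("degenerate input: points are collinear")
  s <- svd(t(P) %*% Q)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- cr - as.vector(R %*% cm)
  moved <- sweep(P %*% t(R), 2, cr, `+`)
  rmsd <- sqrt(mean(rowSums((moved - sweep(Q, 2, cr, `+`))^2)))
  list(R = R, t = t_vec, rmsd = rmsd)
}

#' Superpose one structure onto another over a domain selector
#'
#' The correspondence is the intersection of canonical ids mapped in both
#' structures within the selector, restricted to residues whose fitting atom
#' is present in both (missing atoms are dropped with a note in the result).
#'
#' @param mobile,reference [pmhc_structure] objects.
#' @param mobile_map,reference_map their `pmhc_numbering` maps.
#' @param selector domain selector: one of `"pa"`, `"pb"`, `"ia"`, `"ib"`,
#'   `"peptide"`, `"pab"`, or a character vector of canonical ids.
#' @param atom atom name used for fitting (default `"CA"`).
#' @return a `pmhc_superposition` list: `transform` (R, t), `rmsd`,
#'   `n_fitted`, `correspondence` (canonical ids used), `structure` (the
#'   transformed mobile copy).
#' @export
superpose_by_domain <- function(mobile, mobile_map, reference, reference_map,
                                selector = "pab", atom = "CA") {
  sel_ids <- function(map) {
    if (length(selector) == 1 && selector %in%
        c(DOMAIN_CLASSES, "peptide", "pab")) {
      doms <- if (selector == "pab") c("pa", "pb") else selector
      map$canon[map$domain %in% doms]
    } else selector
  }
  common <- intersect(sel_ids(mobile_map), sel_ids(reference_map))
  xm <- atom_coords(mobile, canon_to_reskey(mobile_map, common), atom)
  xr <- atom_coords(reference, canon_to_reskey(reference_map, common), atom)
  ok <- stats::complete.cases(xm) & stats::complete.cases(xr)
  n_dropped <- sum(!ok)
  if (sum(ok) < 3)
    stop("fewer than 3 shared ", atom, " positions for selector '",
         paste(selector, collapse = ","), "'")
  fit <- kabsch_fit(xm[ok, , drop = FALSE], xr[ok, , drop = FALSE])
  moved <- transform_structure(mobile, fit$R, fit$t)
  structure(list(transform = fit[c("R", "t")], rmsd = fit$rmsd,
                 n_fitted = sum(ok), n_dropped = n_dropped,
                 correspondence = common[ok], selector = selector,
                 structure = moved),
            class = "pmhc_superposition")
}

#' @export
print.pmhc_superposition <- function(x, ...) {
  cat("pmhc_superposition over '", paste(x$selector, collapse = ","), "': ",
      x$n_fitted, " atoms fitted, rmsd = ", sprintf("%.3f", x$rmsd),
      " A\n", sep = "")
  invisible(x)
}
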