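#' @title Backbone hydrogen bonds (Kabsch-Sander model)
#' @description
#' Backbone N-H...O=C hydrogen bonds are assigned with the Kabsch-Sander
#' electrostatic model: partial charges +-0.20 e on N/H and +-0.42 e on C/O
#' give E = 27.888 * (1/d(ON) + 1/d(CH) - 1/d(OH) - 1/d(CN)) kcal/mol, and a
#' bond is accepted when E < -0.5 kcal/mol. Crystal structures lack
#' hydrogens, so the amide H is reconstructed 1.0 A from N along the previous
#' residue's O->C direction, exactly as DSSP does. Proline has no amide
#' donor; chain breaks (C-N > 2.5 A) interrupt H reconstruction.
#' @name hbonds
NULL

KS_Q <- 27.888          # 332 * 0.42 * 0.20 kcal/mol * A
KS_CUTOFF <- -0.5       # accept bonds below this energy
KS_EMIN <- -9.9         # clamp for near-contact geometries
CA_PREFILTER <- 9.0     # CA-CA prefilter radius (lossless; see tests)

# Ordered polymer residue table with backbone coordinates and reconstructed
# amide H. One row per residue that has N, CA, C and O; others are skipped
# with a warning. Columns: chain, resno, icode, resname, reskey, idx,
# continuous (peptide-bonded to previous row), and matrices in attrs.
backbone_frame <- function(st) {
  res <- residue_table(st)
  get1 <- function(name) atom_coords(st, res$reskey, name)
  N <- get1("N"); CA <- get1("CA"); C <- get1("C"); O <- get1("O")
  ok <- stats::complete.cases(N) & stats::complete.cases(CA) &
    stats::complete.cases(C) & stats::complete.cases(O)
  if (any(!ok))
    warning(sum(!ok), " residue(s) skipped: incomplete backbone (",
            paste(utils::head(res$reskey[!ok], 5), collapse = ", "), ")")
  res <- res[ok, , drop = FALSE]
  N <- N[ok, , drop = FALSE]; CA <- CA[ok, , drop = FALSE]
  C <- C[ok, , drop = FALSE]; O <- O[ok, , drop = FALSE]
  n <- nrow(res)
  res$idx <- seq_len(n)
  cont <- rep(FALSE, n)
  if (n > 1) {
    same <- res$chain[-1] == res$chain[-n]
    gap <- sqrt(rowSums((N[-1, , drop = FALSE] - C[-n, , drop = FALSE])^2))
    cont[-1] <- same & gap < 2.5
  }
  H <- matrix(NA_real_, n, 3)
  for (i in which(cont)) {
    co <- C[i - 1, ] - O[i - 1, ]
    H[i, ] <- N[i, ] + co / vnorm(co)
  }
  H[res$resname == "PRO", ] <- NA_real_
  res$continuous <- cont
  attr(res, "N") <- N; attr(res, "CA") <- CA; attr(res, "C") <- C
  attr(res, "O") <- O; attr(res, "H") <- H
  res
}

ks_energy <- function(N_d, H_d, C_a, O_a) {
  dON <- sqrt(sum((O_a - N_d)^2)); dCH <- sqrt(sum((C_a - H_d)^2))
  dOH <- sqrt(sum((O_a - H_d)^2)); dCN <- sqrt(sum((C_a - N_d)^2))
  if (min(dON, dCH, dOH, dCN) < 0.5) return(KS_EMIN)
  e <- KS_Q * (1 / dON + 1 / dCH - 1 / dOH - 1 / dCN)
  max(e, KS_EMIN)
}

#' Compute backbone hydrogen bonds
#'
#' Scans all residue pairs (CA-CA prefilter 9 A by default; the prefilter is
#' lossless, see the package tests) and returns accepted Kabsch-Sander bonds.
#' Within a chain, donor and acceptor must be at least 2 residues apart;
#' inter-chain bonds are always considered.
#'
#' @param st a [pmhc_structure].
#' @param cutoff acceptance threshold, kcal/mol (default -0.5).
#' @param prefilter CA-CA prefilter radius in Angstrom; `Inf` disables it.
#' @return a `pmhc_hbonds` data frame with one row per accepted bond:
#'   `donor_key`, `acceptor_key` (residue keys; donor contributes N-H,
#'   acceptor contributes C=O), `donor_idx`, `acceptor_idx` (indices into the
#'   backbone frame stored in `attr(, "frame")`) and `energy`.
#' @export
compute_backbone_hbonds <- function(st, cutoff = KS_CUTOFF,
                                    prefilter = CA_PREFILTER) {
  fr <- backbone_frame(st)
  n <- nrow(fr)
  N <- attr(fr, "N"); H <- attr(fr, "H"); C <- attr(fr, "C")
  O <- attr(fr, "O"); CA <- attr(fr, "CA")
  out <- list()
  if (n >= 2) {
    d2 <- as.matrix(stats::dist(CA))
    for (don in seq_len(n)) {
      if (anyNA(H[don, ])) next
      cand <- which(d2[don, ] < prefilter)
      for (acc in cand) {
        if (acc == don) next
        if (fr$chain[acc] == fr$chain[don] &&
            abs(fr$idx[acc] - fr$idx[don]) < 2) next
        e <- ks_energy(N[don, ], H[don, ], C[acc, ], O[acc, ])
        if (e < cutoff)
          out[[length(out) + 1]] <- data.frame(
            donor_key = fr$reskey[don], acceptor_key = fr$reskey[acc],
            donor_idx = don, acceptor_idx = acc, energy = e,
            stringsAsFactors = FALSE)
      }
    }
  }
  hb <- if (length(out)) do.call(rbind, out) else
    data.frame(donor_key = character(), acceptor_key = character(),
               donor_idx = integer(), acceptor_idx = integer(),
               energy = numeric(), stringsAsFactors = FALSE)
  hb <- hb[order(hb$donor_idx, hb$acceptor_idx), , drop = FALSE]
  rownames(hb) <- NULL
  attr(hb, "frame") <- fr
  class(hb) <- c("pmhc_hbonds", "data.frame")
  hb
}
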