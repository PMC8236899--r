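#' @title Secondary-structure assignment (DSSP-equivalent)
#' @description
#' Per-residue states are derived from Kabsch-Sander backbone hydrogen bonds
#' with the DSSP pattern rules: an n-turn at residue i is a bond from NH(i+n)
#' to CO(i); two consecutive n-turns make a minimal helix; bridges (parallel
#' or antiparallel) chain into beta-ladders. Reported states are collapsed to
#' the set used in the alignment figures of this field: alpha-helix, 3-10
#' helix, pi-helix, strand, turn/bend and coil. When helix patterns overlap,
#' a pi pattern (minimum length 5) takes precedence over alpha, matching
#' modern DSSP behaviour (>= v3), which is what reproduces the pi-helix call
#' at the H2a/H2b kink of primitive pMHC-I structures; otherwise alpha beats
#' 3-10. Isolated single bridges are kept as bridges, not strands, and
#' reported as coil.
#' @name secondary-structure
NULL

SS_STATES <- c(H = "alpha-helix", G = "310-helix", I = "pi-helix",
               E = "strand", T = "turn", S = "bend", C = "coil")

# logical n x n bond matrix: bond[a, d] TRUE when CO of a accepts from NH of d
hbond_matrix <- function(hbonds, n) {
  m <- matrix(FALSE, n, n)
  if (nrow(hbonds))
    m[cbind(hbonds$acceptor_idx, hbonds$donor_idx)] <- TRUE
  m
}

# residues i..j are consecutive in sequence within one chain
run_continuous <- function(fr, i, j) {
  if (j < i) return(FALSE)
  if (j == i) return(TRUE)
  all(fr$continuous[(i + 1):j])
}

#' Assign secondary-structure states
#'
#' @param hbonds result of [compute_backbone_hbonds()].
#' @param st the same structure (used only for labelling).
#' @return a `pmhc_ss` data frame: one row per backbone-complete residue with
#'   `reskey`, `state` (single-letter H/G/I/E/T/C) and `state_name`.
#' @export
assign_secondary_structure <- function(hbonds, st = NULL) {
  fr <- attr(hbonds, "frame")
  n <- nrow(fr)
  bond <- hbond_matrix(hbonds, n)
  turn <- list()
  for (k in 3:5) {
    t_k <- rep(FALSE, n)
    idx <- seq_len(max(0, n - k))
    for (i in idx)
      t_k[i] <- bond[i, i + k] && run_continuous(fr, i, i + k)
    turn[[as.character(k)]] <- t_k
  }
  helix_flag <- function(k) {
    t_k <- turn[[as.character(k)]]
    fl <- rep(FALSE, n)
    for (i in which(t_k)) {
      if (i > 1 && t_k[i - 1]) fl[i:(i + k - 1)] <- TRUE
    }
    fl
  }
  fl_I <- helix_flag(5); fl_H <- helix_flag(4); fl_G <- helix_flag(3)

  br <- find_bridges(bond, fr)
  ladders <- chain_bridges(br, fr)
  in_ladder <- rep(FALSE, n)
  for (ld in ladders) {
    if (nrow(ld$rungs) >= 2) {
      in_ladder[unlist(ld$rungs[, c("i", "j")])] <- TRUE
    }
  }
  any_turn <- rep(FALSE, n)
  for (k in 3:5) {
    t_k <- turn[[as.character(k)]]
    for (i in which(t_k)) any_turn[(i + 1):(i + k - 1)] <- TRUE
  }

  # kappa bend: virtual CA bond angle over i-2, i, i+2 above 70 degrees
  CAm <- attr(fr, "CA")
  bend <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (i - 2 < 1 || i + 2 > n) next
    if (fr$chain[i - 2] != fr$chain[i] || fr$chain[i + 2] != fr$chain[i]) next
    u <- CAm[i, ] - CAm[i - 2, ]
    v <- CAm[i + 2, ] - CAm[i, ]
    kappa <- rad2deg(acos(max(-1, min(1, sum(u * v) / (vnorm(u) * vnorm(v))))))
    bend[i] <- kappa > 70
  }
  # precedence (low to high): S < T < G < E < H < I; the pi-over-alpha
  # exception follows modern DSSP and the strand/helix order follows classic
  # DSSP summary precedence
  state <- rep("C", n)
  state[bend] <- "S"
  state[any_turn] <- "T"
  state[fl_G] <- "G"
  state[in_ladder] <- "E"
  state[fl_H] <- "H"
  state[fl_I] <- "I"
  out <- data.frame(reskey = fr$reskey, chain = fr$chain, resno = fr$resno,
                    icode = fr$icode, resname = fr$resname, state = state,
                    state_name = unname(SS_STATES[state]),
                    stringsAsFactors = FALSE)
  attr(out, "frame") <- fr
  attr(out, "ladders") <- ladders
  attr(out, "bridges") <- br
  class(out) <- c("pmhc_ss", "data.frame")
  out
}

# Kabsch-Sander bridge detection. bond[a, d]: CO(a) <- NH(d).
find_bridges <- function(bond, fr) {
  n <- nrow(fr)
  hb <- function(a, d) a >= 1 && d >= 1 && a <= n && d <= n && bond[a, d]
  res <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (fr$chain[i] == fr$chain[j] && (j - i) < 3) next
      # both bridge partners need existing, chain-continuous neighbours
      # (terminal residues never form bridges, as in reference DSSP)
      if (i - 1 < 1 || i + 1 > n || j - 1 < 1 || j + 1 > n) next
      if (!run_continuous(fr, i - 1, i + 1) ||
          !run_continuous(fr, j - 1, j + 1)) next
      par <- (hb(i - 1, j) && hb(j, i + 1)) ||
             (hb(j - 1, i) && hb(i, j + 1))
      anti <- (hb(i, j) && hb(j, i)) ||
              (hb(i - 1, j + 1) && hb(j - 1, i + 1))
      if (par || anti)
        res[[length(res) + 1]] <- data.frame(
          i = i, j = j, sense = if (anti) "antiparallel" else "parallel")
    }
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(i = integer(), j = integer(), sense = character())
}

# Chain bridges of equal sense into ladders; then merge ladders linked by a
# beta-bulge (gap of at most 2 residues on one strand and at most 5 on the
# other, DSSP-style). Rungs are kept in strand-a order.
chain_bridges <- function(br, fr) {
  if (!nrow(br)) return(list())
  br <- br[order(br$i, br$j), , drop = FALSE]
  used <- rep(FALSE, nrow(br))
  ladders <- list()
  for (s in seq_len(nrow(br))) {
    if (used[s]) next
    rungs <- br[s, , drop = FALSE]
    used[s] <- TRUE
    repeat {
      last <- rungs[nrow(rungs), ]
      step_j <- if (last$sense == "antiparallel") -1 else 1
      nxt <- which(!used & br$sense == last$sense &
                     br$i == last$i + 1 & br$j == last$j + step_j)
      if (!length(nxt)) break
      rungs <- rbind(rungs, br[nxt[1], , drop = FALSE])
      used[nxt[1]] <- TRUE
    }
    ladders[[length(ladders) + 1]] <-
      list(sense = rungs$sense[1], rungs = rungs[, c("i", "j")])
  }
  merge_bulge_ladders(ladders, fr)
}

merge_bulge_ladders <- function(ladders, fr) {
  if (length(ladders) < 2) return(ladders)
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (a in seq_along(ladders)) {
      for (b in seq_along(ladders)) {
        if (a >= b) next
        la <- ladders[[a]]; lb <- ladders[[b]]
        if (la$sense != lb$sense) next
        ra <- la$rungs; rb <- lb$rungs
        gi <- rb$i[1] - ra$i[nrow(ra)] - 1
        gj <- if (la$sense == "antiparallel")
          ra$j[nrow(ra)] - rb$j[1] - 1 else rb$j[1] - ra$j[nrow(ra)] - 1
        if (gi < 0 || gj < 0) next
        if (!run_continuous(fr, ra$i[nrow(ra)], rb$i[1])) next
        if (min(gi, gj) <= 2 && max(gi, gj) <= 5) {
          ladders[[a]]$rungs <- rbind(ra, rb)
          ladders[[b]] <- NULL
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
  }
  ladders
}
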