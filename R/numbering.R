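#' @title Canonical domain nomenclature and numbering
#' @description
#' MHC-I and MHC-II ectodomains are compared under a unified nomenclature:
#' the two halves of the peptide-binding superdomain are `pa` (I-alpha1 or
#' II-alpha1) and `pb` (I-alpha2 or II-beta1), and the two membrane-proximal
#' IgSF C1 domains are `ia` (beta-2-microglobulin or II-alpha2) and `ib`
#' (I-alpha3 or II-beta2); `pab` selects pa+pb. Canonical per-domain positions
#' (rooted in the classic HLA-A2 numbering, with lowercase insertion codes
#' such as `pb90b`) and the peptide register P1..P-omega are attached to a
#' structure through an explicit per-structure configuration, because the
#' underlying alignment is hand-curated and not inferable at runtime.
#' @name canonical-numbering
NULL

DOMAIN_CLASSES <- c("pa", "pb", "ia", "ib")

#' Parse a canonical residue identifier string
#'
#' Accepts domain positions such as `"pa45"` or `"pb90b"` (lowercase trailing
#' letter = insertion code) and peptide registers such as `"P1"`, `"P9"`,
#' `"P-2"`.
#'
#' @param id character scalar.
#' @return list with `domain` (`"pa"`, `"pb"`, `"ia"`, `"ib"` or
#'   `"peptide"`), `pos` (integer; register index for peptide ids) and
#'   `icode`.
#' @export
canonical_id <- function(id) {
  if (grepl("^P-?[0-9]+$", id)) {
    return(list(domain = "peptide",
                pos = as.integer(sub("^P", "", id)), icode = ""))
  }
  m <- regmatches(id, regexec("^(pa|pb|ia|ib)([0-9]+)([a-z]?)$", id))[[1]]
  if (length(m) == 0) stop("not a canonical residue id: ", id)
  list(domain = m[2], pos = as.integer(m[3]), icode = m[4])
}

#' Build the author-to-canonical numbering map for one structure
#'
#' The configuration lists, per domain, the author chain and inclusive author
#' residue range(s) with the canonical position of each range start, plus an
#' optional insertion table for positions carrying canonical insertion codes.
#' The peptide entry anchors the register by the author number of P1 and of
#' the C-terminal core residue P-omega.
#'
#' @param st a [pmhc_structure].
#' @param config a list (typically from [read_numbering_config()]) with
#'   elements `class_label` (`"MHC-I"` or `"MHC-II"`), `domains` (named list
#'   `pa`/`pb`/`ia`/`ib`, each either `list(chain, start, end, canon_start)`
#'   or `list(chain, ranges = list(...))`), optional
#'   `peptide = list(chain, p1, omega)` and optional `insertions`, a list of
#'   `list(domain, resno, icode, canon_pos, canon_icode)` overrides.
#' @return a `pmhc_numbering` data frame mapping
#'   `(chain, resno, icode) <-> (domain, canon_pos, canon_icode, register)`,
#'   with unmapped polymer residues recorded in `attr(, "unmapped")`.
#' @export
build_numbering_map <- function(st, config) {
  doms <- config$domains
  if (is.null(doms) || !length(doms)) stop("config has no domain entries")
  bad <- setdiff(names(doms), DOMAIN_CLASSES)
  if (length(bad)) stop("unknown domain class in config: ",
                        paste(bad, collapse = ", "))
  rows <- list()
  for (dname in names(doms)) {
    d <- doms[[dname]]
    ranges <- if (!is.null(d$ranges)) d$ranges else
      list(list(start = d$start, end = d$end,
                canon_start = if (is.null(d$canon_start)) 1 else d$canon_start))
    for (r in ranges) {
      cstart <- if (is.null(r$canon_start)) 1 else r$canon_start
      if (r$end < r$start) stop("bad range for domain ", dname)
      resno <- seq(r$start, r$end)
      rows[[length(rows) + 1]] <- data.frame(
        chain = d$chain, resno = resno, icode = "",
        domain = dname, canon_pos = cstart + resno - r$start,
        canon_icode = "", register = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  map <- do.call(rbind, rows)

  # explicit insertion-code / override table
  for (ins in config$insertions) {
    i <- which(map$chain == map$chain[map$domain == ins$domain][1] &
               map$domain == ins$domain & map$resno == ins$resno &
               map$icode == (if (is.null(ins$icode)) "" else ins$icode))
    row <- data.frame(chain = doms[[ins$domain]]$chain, resno = ins$resno,
                      icode = if (is.null(ins$icode)) "" else ins$icode,
                      domain = ins$domain, canon_pos = ins$canon_pos,
                      canon_icode = if (is.null(ins$canon_icode)) "" else
                        ins$canon_icode,
                      register = NA_integer_, stringsAsFactors = FALSE)
    if (length(i)) map[i, ] <- row else map <- rbind(map, row)
  }

  pep <- config$peptide
  if (!is.null(pep)) {
    pres <- residue_table(st)
    pres <- pres[pres$chain == pep$chain, , drop = FALSE]
    if (nrow(pres)) {
      reg <- pres$resno - pep$p1 + 1L
      reg[reg <= 0] <- reg[reg <= 0] - 1L   # ...P-2, P-1, P1... (no P0)
      rows_p <- data.frame(chain = pep$chain, resno = pres$resno,
                           icode = pres$icode, domain = "peptide",
                           canon_pos = reg, canon_icode = "", register = reg,
                           stringsAsFactors = FALSE)
      map <- rbind(map, rows_p)
    }
  }

  akey <- residue_key(map$chain, map$resno, map$icode)
  if (anyDuplicated(akey))
    stop("overlapping author ranges in numbering config: ",
         paste(unique(akey[duplicated(akey)]), collapse = ", "))
  ckey <- paste0(map$domain, ":", map$canon_pos, map$canon_icode)
  if (anyDuplicated(ckey))
    stop("canonical position assigned twice in config: ",
         paste(unique(ckey[duplicated(ckey)]), collapse = ", "))
  map$reskey <- akey
  map$canon <- ifelse(map$domain == "peptide",
                      paste0("P", map$register),
                      paste0(map$domain, map$canon_pos, map$canon_icode))

  present <- map$reskey %in% residue_table(st)$reskey
  map <- map[present, , drop = FALSE]
  rownames(map) <- NULL
  poly <- residue_table(st)
  unmapped <- setdiff(poly$reskey, map$reskey)
  if (length(unmapped))
    message(length(unmapped), " polymer residue(s) not covered by the ",
            "numbering config: ", paste(utils::head(unmapped, 8),
                                        collapse = ", "),
            if (length(unmapped) > 8) " ..." else "")
  attr(map, "unmapped") <- unmapped
  attr(map, "class_label") <- config$class_label
  attr(map, "omega") <- if (!is.null(pep) && !is.null(pep$omega))
    pep$omega - pep$p1 + 1L else NA_integer_
  class(map) <- c("pmhc_numbering", "data.frame")
  map
}

#' Read a YAML numbering configuration
#' @param path file path to a per-structure YAML document.
#' @return configuration list suitable for [build_numbering_map()].
#' @export
read_numbering_config <- function(path) {
  if (!file.exists(path)) stop("no such numbering config: ", path)
  yaml::read_yaml(path)
}

# Look up author residue key(s) for canonical id strings (e.g. "pa45", "P1").
canon_to_reskey <- function(map, ids) {
  idx <- match(ids, map$canon)
  if (anyNA(idx))
    stop("canonical id(s) not mapped in this structure: ",
         paste(ids[is.na(idx)], collapse = ", "))
  map$reskey[idx]
}

#' Partition mapped residues into the five canonical domains
#'
#' @param st a [pmhc_structure].
#' @param map a `pmhc_numbering` from [build_numbering_map()].
#' @return a `pmhc_domains` list of residue-key vectors (`pa`, `pb`, `ia`,
#'   `ib`, `peptide`) plus the union selector `pab`; the five sets are
#'   pairwise disjoint and cover exactly the mapped residues.
#' @export
assign_domains <- function(st, map) {
  poly <- residue_table(st)$reskey
  missing <- setdiff(map$reskey, poly)
  if (length(missing))
    stop("numbering map refers to residues absent from the structure: ",
         paste(utils::head(missing, 5), collapse = ", "))
  out <- lapply(c(DOMAIN_CLASSES, "peptide"), function(d)
    map$reskey[map$domain == d])
  names(out) <- c(DOMAIN_CLASSES, "peptide")
  out$pab <- c(out$pa, out$pb)
  structure(out, class = "pmhc_domains")
}

#' @export
print.pmhc_domains <- function(x, ...) {
  cat("pmhc_domains:",
      paste(sprintf("%s=%d", names(x), lengths(x)), collapse = ", "), "\n")
  invisible(x)
}
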