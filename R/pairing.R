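#' @title Hydrogen-bond detection and base pair / quartet classification
#' @description
#' Hydrogen bonds are detected from geometry (N/O donor with attached
#' hydrogen, N/O acceptor, donor-acceptor distance and donor-H-acceptor
#' angle cutoffs). Base pairs are classified against a shipped
#' donor/acceptor pattern table (Watson-Crick G-C; G-G N1-carbonyl
#' symmetric; G-A N1-N7 carbonyl-amino; Hoogsteen G-I). Quartets are
#' assembled from classified pairs plus the class-specific cross-links:
#' GAGA (A amino to G N7), minor-groove GCGC (G amino to C O2),
#' major-groove GCGC (C amino to G O6) and cyclic GGGG.
#' @name pairing
NULL

.BASE_LETTER <- c(DA = "A", DC = "C", DG = "G", DT = "T", DI = "I")

# heavy-atom donor fallback when the model carries no hydrogens
.HEAVY_DONORS <- list(DG = c("N1", "N2"), DA = c("N6"), DC = c("N4"),
                      DT = c("N3"), DI = c("N1"))

#' Detect hydrogen bonds in one model
#'
#' With explicit hydrogens (NMR ensembles): each hydrogen is assigned to
#' its nearest heavy atom (within 1.8 Angstrom); N/O parents become
#' donors. Acceptors are N/O atoms of other residues; a bond is kept when
#' the
#' donor-acceptor distance is at most `d_max` and the donor-H-acceptor
#' angle at least `theta_min`. Without hydrogens a per-base heavy-atom
#' donor list with the distance criterion alone is used.
#'
#' @param model model atom table from [get_model()]
#' @param d_max donor-acceptor distance cutoff (Angstrom)
#' @param theta_min minimum donor-H-acceptor angle (degrees)
#' @param base_only restrict to base atoms (exclude sugar-phosphate)
#' @return data.frame, one row per bond, sorted by donor then acceptor:
#'   chain_d, res_d, restype_d, donor, hydrogen, chain_a, res_a, restype_a,
#'   acceptor, distance, theta
#' @export
find_hbonds <- function(model, d_max = 3.5, theta_min = 120,
                        base_only = TRUE) {
  m <- model
  if (base_only) {
    m <- m[!grepl("'", m$atom) & !(m$atom %in% c("P", "OP1", "OP2", "OP3")), ]
  }
  key <- paste(m$chain, m$resno)
  heavy <- m[m$element %in% c("N", "O"), , drop = FALSE]
  allheavy <- m[m$element != "H", , drop = FALSE]
  hyd <- m[m$element == "H", , drop = FALSE]
  has_h <- nrow(hyd) > 0
  donors <- list()
  if (has_h) {
    hk <- paste(hyd$chain, hyd$resno)
    for (i in seq_len(nrow(hyd))) {
      # parent = nearest heavy atom of any element; only N/O parents donate
      cand <- allheavy[paste(allheavy$chain, allheavy$resno) == hk[i], ,
                       drop = FALSE]
      if (!nrow(cand)) next
      d <- sqrt((cand$x - hyd$x[i])^2 + (cand$y - hyd$y[i])^2 +
                  (cand$z - hyd$z[i])^2)
      j <- which.min(d)
      if (d[j] <= 1.8 && cand$element[j] %in% c("N", "O")) {
        donors[[length(donors) + 1L]] <- cbind(cand[j, , drop = FALSE],
                                               data.frame(h_atom = hyd$atom[i],
                                                          hx = hyd$x[i],
                                                          hy = hyd$y[i],
                                                          hz = hyd$z[i]))
      }
    }
    don <- do.call(rbind, donors)
  } else {
    sel <- mapply(function(rt, a) a %in% (.HEAVY_DONORS[[rt]] %||% character(0)),
                  heavy$restype, heavy$atom)
    don <- heavy[sel, , drop = FALSE]
    if (nrow(don)) {
      don$h_atom <- NA_character_
      don$hx <- NA_real_; don$hy <- NA_real_; don$hz <- NA_real_
    }
  }
  out <- list()
  if (!is.null(don) && nrow(don)) {
    dk <- paste(don$chain, don$resno)
    for (i in seq_len(nrow(don))) {
      acc <- heavy[paste(heavy$chain, heavy$resno) != dk[i], , drop = FALSE]
      if (!nrow(acc)) next
      d <- sqrt((acc$x - don$x[i])^2 + (acc$y - don$y[i])^2 +
                  (acc$z - don$z[i])^2)
      keep <- which(d <= d_max)
      for (j in keep) {
        theta <- NA_real_
        if (!is.na(don$h_atom[i])) {
          v1 <- c(don$x[i] - don$hx[i], don$y[i] - don$hy[i],
                  don$z[i] - don$hz[i])
          v2 <- c(acc$x[j] - don$hx[i], acc$y[j] - don$hy[i],
                  acc$z[j] - don$hz[i])
          theta <- .rad2deg(acos(max(-1, min(1, sum(v1 * v2) /
                                               (.vnorm(v1) * .vnorm(v2))))))
          if (theta < theta_min) next
        }
        out[[length(out) + 1L]] <- data.frame(
          chain_d = don$chain[i], res_d = don$resno[i],
          restype_d = don$restype[i], donor = don$atom[i],
          hydrogen = don$h_atom[i],
          chain_a = acc$chain[j], res_a = acc$resno[j],
          restype_a = acc$restype[j], acceptor = acc$atom[j],
          distance = d[j], theta = theta, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out) %||% data.frame(
    chain_d = character(0), res_d = numeric(0), restype_d = character(0),
    donor = character(0), hydrogen = character(0), chain_a = character(0),
    res_a = numeric(0), restype_a = character(0), acceptor = character(0),
    distance = numeric(0), theta = numeric(0))
  res <- res[order(res$chain_d, res$res_d, res$donor,
                   res$chain_a, res$res_a, res$acceptor), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.pair_patterns <- function() {
  tab <- .pkg_env$pair_patterns
  if (is.null(tab)) {
    tab <- utils::read.delim(.extdata("pair_patterns.tsv"),
                             comment.char = "#", stringsAsFactors = FALSE)
    .pkg_env$pair_patterns <- tab
  }
  tab
}

.hbonds_between <- function(hbonds, ri, rj) {
  ki <- paste(ri[1], ri[2]); kj <- paste(rj[1], rj[2])
  kd <- paste(hbonds$chain_d, hbonds$res_d)
  ka <- paste(hbonds$chain_a, hbonds$res_a)
  hbonds[(kd == ki & ka == kj) | (kd == kj & ka == ki), , drop = FALSE]
}

#' Classify one base pair
#'
#' Matches the hydrogen bonds between two residues against the pattern
#' table (`extdata/pair_patterns.tsv`); a class is assigned when at least
#' the class's minimum number of pattern bonds is observed, otherwise the
#' bonded pair is labelled `OTHER`. Symmetric in the residue order.
#'
#' @param model model atom table
#' @param res_i,res_j residues as `c(chain, resno)`
#' @param hbonds hydrogen-bond table from [find_hbonds()]
#' @return one-row data.frame: chain_i, res_i, chain_j, res_j, class,
#'   n_hbonds, strand_relation
#' @export
classify_pair <- function(model, res_i, res_j, hbonds) {
  hb <- .hbonds_between(hbonds, res_i, res_j)
  pat <- .pair_patterns()
  bl <- function(rt) .BASE_LETTER[[rt]] %||% "?"
  counts <- integer(0)
  if (nrow(hb)) {
    sig <- paste(vapply(hb$restype_d, bl, character(1)), hb$donor,
                 vapply(hb$restype_a, bl, character(1)), hb$acceptor)
    psig <- paste(pat$base_d, pat$donor, pat$base_a, pat$acceptor)
    hits <- pat[match(sig, psig), "class"]
    hits <- hits[!is.na(hits)]
    counts <- table(hits)
  }
  cls <- "OTHER"
  if (length(counts)) {
    minb <- vapply(names(counts), function(cl)
      min(pat$min_bonds[pat$class == cl]), numeric(1))
    ok <- names(counts)[counts >= minb]
    if (length(ok)) {
      prio <- c("WC_GC", "GG_N1_CARBONYL", "GA_N1N7_CARBONYLAMINO",
                "G_I_HOOGSTEEN")
      ok <- ok[order(-counts[ok], match(ok, prio))]
      cls <- ok[1]
    }
  }
  rel <- "intramolecular"
  if (res_i[1] != res_j[1]) {
    sub_i <- model[model$chain == res_i[1] & model$resno == as.numeric(res_i[2]), ]
    sub_j <- model[model$chain == res_j[1] & model$resno == as.numeric(res_j[2]), ]
    zi <- fit_base_frame(sub_i)$axes[, 3]
    zj <- fit_base_frame(sub_j)$axes[, 3]
    rel <- if (sum(zi * zj) < 0) "antiparallel" else "parallel"
  }
  data.frame(chain_i = res_i[1], res_i = as.numeric(res_i[2]),
             chain_j = res_j[1], res_j = as.numeric(res_j[2]),
             class = cls, n_hbonds = nrow(hb), strand_relation = rel,
             stringsAsFactors = FALSE)
}

#' Find and classify all base pairs of a model
#'
#' Every residue pair linked by at least two detected hydrogen bonds is
#' classified. Residue order within a pair is canonical (chain, resno).
#'
#' @param model model atom table
#' @param hbonds optional precomputed table from [find_hbonds()]
#' @param ... passed to [find_hbonds()]
#' @return data.frame of classified pairs
#' @export
find_pairs <- function(model, hbonds = NULL, ...) {
  if (is.null(hbonds)) hbonds <- find_hbonds(model, ...)
  if (!nrow(hbonds)) {
    return(data.frame(chain_i = character(0), res_i = numeric(0),
                      chain_j = character(0), res_j = numeric(0),
                      class = character(0), n_hbonds = integer(0),
                      strand_relation = character(0)))
  }
  kd <- paste(hbonds$chain_d, hbonds$res_d)
  ka <- paste(hbonds$chain_a, hbonds$res_a)
  lo <- ifelse(kd < ka, kd, ka)
  hi <- ifelse(kd < ka, ka, kd)
  pk <- paste(lo, hi, sep = "|")
  cnt <- table(pk)
  cand <- names(cnt)[cnt >= 2]
  out <- lapply(sort(cand), function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    ri <- strsplit(parts[1], " ")[[1]]
    rj <- strsplit(parts[2], " ")[[1]]
    classify_pair(model, ri, rj, hbonds)
  })
  res <- do.call(rbind, out) %||%
    data.frame(chain_i = character(0), res_i = numeric(0),
               chain_j = character(0), res_j = numeric(0),
               class = character(0), n_hbonds = integer(0),
               strand_relation = character(0))
  rownames(res) <- NULL
  res
}

.res_key <- function(chain, resno) paste0(chain, ":", resno)

# cross-link counter: hydrogen bonds between residues of pair a and pair b
# matching (donor_atom -> acceptor_atom) with given donor/acceptor bases
.count_cross <- function(hbonds, resa, resb, donor, acceptor,
                         base_d = NULL, base_a = NULL) {
  keys_a <- vapply(resa, function(r) paste(r[1], r[2]), character(1))
  keys_b <- vapply(resb, function(r) paste(r[1], r[2]), character(1))
  kd <- paste(hbonds$chain_d, hbonds$res_d)
  ka <- paste(hbonds$chain_a, hbonds$res_a)
  sel <- ((kd %in% keys_a & ka %in% keys_b) |
            (kd %in% keys_b & ka %in% keys_a)) &
    hbonds$donor == donor & hbonds$acceptor == acceptor
  if (!is.null(base_d))
    sel <- sel & vapply(hbonds$restype_d, function(rt)
      (.BASE_LETTER[[rt]] %||% "?") == base_d, logical(1))
  if (!is.null(base_a))
    sel <- sel & vapply(hbonds$restype_a, function(rt)
      (.BASE_LETTER[[rt]] %||% "?") == base_a, logical(1))
  sum(sel)
}

#' Assemble quartets from classified pairs and hydrogen bonds
#'
#' Class rules: GAGA = two G-A (N1-N7 carbonyl-amino) pairs cross-linked by
#' at least two A-amino to G-N7 bonds; GCGC_MINOR = two Watson-Crick G-C
#' pairs with reciprocal G-amino to C-O2 cross-links; GCGC_MAJOR = the same
#' with C-amino to G-O6 cross-links; GGGG = four guanines in a cyclic
#' donor-to-acceptor (N1 to O6 / N2 to N7) arrangement. Each residue joins
#' at most one quartet per model; conflicts are resolved by maximal total
#' hydrogen-bond count, then lowest residue indices.
#'
#' @param model model atom table
#' @param pairs classified pairs from [find_pairs()]
#' @param hbonds hydrogen bonds from [find_hbonds()]
#' @return data.frame: quartet_class, residues (comma-joined chain:resno),
#'   n_hbonds, and the two constituent pairs
#' @export
assemble_quartets <- function(model, pairs, hbonds) {
  cand <- list()
  if (nrow(pairs) >= 2) {
    pr <- function(k) list(c(pairs$chain_i[k], pairs$res_i[k]),
                           c(pairs$chain_j[k], pairs$res_j[k]))
    idx <- which(pairs$class %in% c("WC_GC", "GA_N1N7_CARBONYLAMINO"))
    if (length(idx) >= 2) {
      cmb <- utils::combn(idx, 2)
      for (c1 in seq_len(ncol(cmb))) {
        a <- cmb[1, c1]; b <- cmb[2, c1]
        if (pairs$class[a] != pairs$class[b]) next
        resa <- pr(a); resb <- pr(b)
        if (length(unique(c(vapply(resa, paste, character(1), collapse = ":"),
                            vapply(resb, paste, character(1), collapse = ":")))) < 4) next
        if (pairs$class[a] == "GA_N1N7_CARBONYLAMINO") {
          nx <- .count_cross(hbonds, resa, resb, "N6", "N7", "A", "G")
          if (nx >= 2) {
            cand[[length(cand) + 1L]] <- list(class = "GAGA", a = a, b = b,
                                              cross = nx)
          }
        } else {
          nmin <- .count_cross(hbonds, resa, resb, "N2", "O2", "G", "C")
          nmaj <- .count_cross(hbonds, resa, resb, "N4", "O6", "C", "G")
          if (max(nmin, nmaj) >= 2) {
            cand[[length(cand) + 1L]] <- list(
              class = if (nmin >= nmaj) "GCGC_MINOR" else "GCGC_MAJOR",
              a = a, b = b, cross = max(nmin, nmaj))
          }
        }
      }
    }
  }
  # GGGG: directed 4-cycles in the guanine Hoogsteen-edge bond graph
  gb <- hbonds[hbonds$restype_d == "DG" & hbonds$restype_a == "DG" &
                 ((hbonds$donor == "N1" & hbonds$acceptor == "O6") |
                    (hbonds$donor == "N2" & hbonds$acceptor == "N7")), ,
               drop = FALSE]
  gg_cycles <- list()
  if (nrow(gb)) {
    edges <- unique(data.frame(from = paste(gb$chain_d, gb$res_d),
                               to = paste(gb$chain_a, gb$res_a),
                               stringsAsFactors = FALSE))
    adj <- split(edges$to, edges$from)
    nodes <- sort(unique(c(edges$from, edges$to)))
    seen <- character(0)
    for (n1 in nodes) for (n2 in adj[[n1]] %||% character(0)) {
      if (n2 == n1) next
      for (n3 in adj[[n2]] %||% character(0)) {
        if (n3 %in% c(n1, n2)) next
        for (n4 in adj[[n3]] %||% character(0)) {
          if (n4 %in% c(n1, n2, n3)) next
          if (n1 %in% (adj[[n4]] %||% character(0))) {
            key <- paste(sort(c(n1, n2, n3, n4)), collapse = "|")
            if (key %in% seen) next
            seen <- c(seen, key)
            gg_cycles[[length(gg_cycles) + 1L]] <- c(n1, n2, n3, n4)
          }
        }
      }
    }
  }
  rows <- list()
  for (cc in cand) {
    a <- cc$a; b <- cc$b
    resnames <- c(.res_key(pairs$chain_i[a], pairs$res_i[a]),
                  .res_key(pairs$chain_j[a], pairs$res_j[a]),
                  .res_key(pairs$chain_i[b], pairs$res_i[b]),
                  .res_key(pairs$chain_j[b], pairs$res_j[b]))
    rows[[length(rows) + 1L]] <- data.frame(
      quartet_class = cc$class,
      residues = paste(resnames, collapse = ","),
      n_hbonds = pairs$n_hbonds[a] + pairs$n_hbonds[b] + cc$cross,
      pair_a = paste(resnames[1:2], collapse = "-"),
      pair_b = paste(resnames[3:4], collapse = "-"),
      stringsAsFactors = FALSE)
  }
  for (cy in gg_cycles) {
    resnames <- vapply(cy, function(k) sub(" ", ":", k), character(1))
    nb <- sum(paste(gb$chain_d, gb$res_d) %in% cy &
                paste(gb$chain_a, gb$res_a) %in% cy)
    rows[[length(rows) + 1L]] <- data.frame(
      quartet_class = "GGGG", residues = paste(resnames, collapse = ","),
      n_hbonds = nb,
      pair_a = paste(resnames[1:2], collapse = "-"),
      pair_b = paste(resnames[3:4], collapse = "-"),
      stringsAsFactors = FALSE)
  }
  qt <- do.call(rbind, rows) %||%
    data.frame(quartet_class = character(0), residues = character(0),
               n_hbonds = integer(0), pair_a = character(0),
               pair_b = character(0))
  if (nrow(qt) <= 1) { rownames(qt) <- NULL; return(qt) }
  # conflict resolution: greedy by hydrogen-bond count, then residue order
  qt <- qt[order(-qt$n_hbonds, qt$residues), , drop = FALSE]
  used <- character(0)
  keep <- logical(nrow(qt))
  for (i in seq_len(nrow(qt))) {
    rs <- strsplit(qt$residues[i], ",", fixed = TRUE)[[1]]
    if (!any(rs %in% used)) {
      keep[i] <- TRUE
      used <- c(used, rs)
    }
  }
  qt <- qt[keep, , drop = FALSE]
  qt <- qt[order(qt$residues), , drop = FALSE]
  rownames(qt) <- NULL
  qt
}

#' Detect crisscross pair couples
#'
#' Reports stacked couples of base pairs that join the same two strands and
#' whose inter-pair twist magnitude is at least `twist_min` degrees -- the
#' arrangement adopted by terminal and groove-flanking G-G pairs in
#' AGCGA-quadruplexes (characteristic twists of 40-60 degrees).
#'
#' @param model model atom table
#' @param pairs classified pairs from [find_pairs()]
#' @param twist_min minimum |twist| (degrees)
#' @param max_center_dist maximum pair-center separation for "stacked"
#' @return data.frame pair_a, pair_b, twist, rise
#' @export
detect_crisscross <- function(model, pairs, twist_min = 35,
                              max_center_dist = 6.5) {
  if (nrow(pairs) < 2) {
    return(data.frame(pair_a = character(0), pair_b = character(0),
                      twist = numeric(0), rise = numeric(0)))
  }
  frames <- base_frames(model)
  pf <- lapply(seq_len(nrow(pairs)), function(k) {
    fi <- frames[[.res_key(pairs$chain_i[k], pairs$res_i[k])]]
    fj <- frames[[.res_key(pairs$chain_j[k], pairs$res_j[k])]]
    pair_frame(fi, fj)
  })
  pchains <- lapply(seq_len(nrow(pairs)), function(k)
    sort(c(pairs$chain_i[k], pairs$chain_j[k])))
  out <- list()
  cmb <- utils::combn(nrow(pairs), 2)
  for (c1 in seq_len(ncol(cmb))) {
    a <- cmb[1, c1]; b <- cmb[2, c1]
    if (!identical(pchains[[a]], pchains[[b]])) next
    dc <- .vnorm(pf[[a]]$origin - pf[[b]]$origin)
    if (dc > max_center_dist) next
    st <- step_params(pf[[a]], pf[[b]])
    if (abs(st["twist"]) >= twist_min) {
      out[[length(out) + 1L]] <- data.frame(
        pair_a = paste(.res_key(pairs$chain_i[a], pairs$res_i[a]),
                       .res_key(pairs$chain_j[a], pairs$res_j[a]), sep = "-"),
        pair_b = paste(.res_key(pairs$chain_i[b], pairs$res_i[b]),
                       .res_key(pairs$chain_j[b], pairs$res_j[b]), sep = "-"),
        twist = unname(st["twist"]), rise = unname(st["rise"]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out) %||%
    data.frame(pair_a = character(0), pair_b = character(0),
               twist = numeric(0), rise = numeric(0))
  rownames(res) <- NULL
  res
}

#' Consensus of per-model pair (or quartet) tables
#'
#' An entry is retained when it occurs, with identical identity columns, in
#' at least `frac` of the models.
#' @param tables list of per-model data.frames
#' @param id_cols columns defining identity
#' @param frac minimum fraction of models (default 0.5)
#' @return consensus data.frame with an `n_models` support column
#' @export
consensus_table <- function(tables, id_cols, frac = 0.5) {
  n <- length(tables)
  all <- do.call(rbind, lapply(tables, function(t) t[, id_cols, drop = FALSE]))
  if (is.null(all) || !nrow(all)) {
    out <- tables[[1]][0, id_cols, drop = FALSE]
    out$n_models <- integer(0)
    return(out)
  }
  key <- do.call(paste, c(all, sep = "|"))
  cnt <- table(key)
  keep <- names(cnt)[cnt >= frac * n]
  out <- unique(all[key %in% keep, , drop = FALSE])
  out$n_models <- as.integer(cnt[do.call(paste, c(out, sep = "|"))])
  rownames(out) <- NULL
  out[order(do.call(paste, c(out[id_cols], sep = "|"))), , drop = FALSE]
}
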