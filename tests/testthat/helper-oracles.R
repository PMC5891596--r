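## Independent oracles used across the suite.  These deliberately avoid the
## package's own term machinery (mm_energy, term_filter, enumerate_terms):
## raw loops, own graph distances, own trigonometry.

FIXTURES <- c("ethanol_methanol", "propane_two_junctions", "butane_bonded_cl")

## central finite differences of a scalar function of an n x 3 matrix
fd_gradient <- function(f, x, h = 1e-5) {
  g <- x * 0
  for (a in seq_len(nrow(x))) for (c in 1:3) {
    xp <- x; xp[a, c] <- xp[a, c] + h
    xm <- x; xm[a, c] <- xm[a, c] - h
    g[a, c] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

## all-pairs topological distance by BFS over an explicit bond list
graph_dist <- function(bond_mat, n) {
  adj <- lapply(seq_len(n), function(i)
    c(bond_mat[bond_mat[, 1] == i, 2], bond_mat[bond_mat[, 2] == i, 1]))
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (src in seq_len(n)) {
    front <- src
    for (step in 1:3) {
      nxt <- setdiff(unique(unlist(adj[front])), which(d[src, ] <= step))
      nxt <- nxt[d[src, nxt] > step]
      d[src, nxt] <- step
      front <- nxt
      if (!length(front)) break
    }
  }
  d
}

lj_pair_energy <- function(rh1, e1, rh2, e2, r, scale = 1) {
  rmin <- rh1 + rh2; eps <- sqrt(e1 * e2)
  if (eps == 0) return(0)
  s6 <- (rmin / r)^6
  eps * (s6^2 - 2 * s6) / scale
}

angle_of <- function(a, b, c) {
  u <- a - b; v <- c - b
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
}

torsion_of <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  atan2(sum(cr(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
}

## Brute-force enumeration of the terms that fail to cancel between
## E_MM12,q1=0 and E_MM1,q1=0 in the subtractive scheme:
##  (a) intra-QM van der Waals pairs, CL representation (full-system
##      connectivity/scaling) minus HL representation (truncated
##      connectivity), and
##  (b) for covalently bonded CL pairs, the bonded terms removed from the
##      truncated topology (they survive once in E_MM12).
brute_link_correction <- function(fx) {
  top <- fx$topology
  x <- as.matrix(fx$structure)
  n <- nrow(top$atoms)
  reg <- fx$region_map$region
  ls <- fx$link_specs
  ljt <- function(type) {
    r <- top$lj[top$lj$type == type, ]
    c(r$rmin_half, r$eps)
  }
  full_bonds <- cbind(top$bonds$i, top$bonds$j)
  dfull <- graph_dist(full_bonds, n)

  ## (a) CL-side: QM-QM pairs of the full system
  e_cl <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (reg[i] != "QM" || reg[j] != "QM") next
    if (dfull[i, j] <= 2) next
    sc <- if (dfull[i, j] == 3) top$scnb else 1
    p1 <- ljt(top$atoms$type[i]); p2 <- ljt(top$atoms$type[j])
    e_cl <- e_cl + lj_pair_energy(p1[1], p1[2], p2[1], p2[2],
                                  sqrt(sum((x[i, ] - x[j, ])^2)), sc)
  }

  ## HL-side: truncated system with own connectivity and HL coordinates
  qm_idx <- which(reg == "QM")
  xs <- x[qm_idx, , drop = FALSE]
  types <- top$atoms$type[qm_idx]
  clcl <- fx$region_map$cl_cl_bonds
  for (r in seq_len(nrow(ls))) {
    row <- match(ls$cl[r], qm_idx)
    xs[row, ] <- x[ls$q1[r], ] + ls$g[r] * (x[ls$cl[r], ] - x[ls$q1[r], ])
    types[row] <- ls$hl_type[r]
  }
  keep <- reg[top$bonds$i] == "QM" & reg[top$bonds$j] == "QM"
  if (nrow(clcl) > 0)
    for (r in seq_len(nrow(clcl)))
      keep <- keep & !((top$bonds$i == clcl$i[r] & top$bonds$j == clcl$j[r]) |
                       (top$bonds$i == clcl$j[r] & top$bonds$j == clcl$i[r]))
  tb <- cbind(match(top$bonds$i[keep], qm_idx), match(top$bonds$j[keep], qm_idx))
  dtr <- graph_dist(tb, length(qm_idx))
  e_hl <- 0
  for (i in seq_len(length(qm_idx) - 1)) for (j in (i + 1):length(qm_idx)) {
    if (dtr[i, j] <= 2) next
    sc <- if (dtr[i, j] == 3) top$scnb else 1
    p1 <- ljt(types[i]); p2 <- ljt(types[j])
    e_hl <- e_hl + lj_pair_energy(p1[1], p1[2], p2[1], p2[2],
                                  sqrt(sum((xs[i, ] - xs[j, ])^2)), sc)
  }

  ## (b) cross-junction bonded remainder (CL representation, full system)
  e_bonded <- 0
  if (nrow(clcl) > 0) {
    spans <- function(v) any(vapply(seq_len(length(v) - 1), function(s)
      any((v[s] == clcl$i & v[s + 1] == clcl$j) |
          (v[s] == clcl$j & v[s + 1] == clcl$i)), logical(1)))
    b <- top$bonds
    for (r in seq_len(nrow(b))) {
      v <- c(b$i[r], b$j[r])
      if (all(reg[v] == "QM") && spans(v))
        e_bonded <- e_bonded +
          b$kb[r] * (sqrt(sum((x[v[1], ] - x[v[2], ])^2)) - b$r0[r])^2
    }
    a <- top$angles
    for (r in seq_len(nrow(a))) {
      v <- c(a$i[r], a$j[r], a$k[r])
      if (all(reg[v] == "QM") && spans(v))
        e_bonded <- e_bonded +
          a$kth[r] * (angle_of(x[v[1], ], x[v[2], ], x[v[3], ]) - a$th0[r])^2
    }
    d <- top$dihedrals
    for (r in seq_len(nrow(d))) {
      v <- c(d$i[r], d$j[r], d$k[r], d$l[r])
      if (all(reg[v] == "QM") && spans(v))
        e_bonded <- e_bonded + d$vn2[r] *
          (1 + cos(d$per[r] * torsion_of(x[v[1], ], x[v[2], ], x[v[3], ], x[v[4], ]) -
                     d$phase[r]))
    }
  }
  (e_cl + e_bonded) - e_hl
}

## intra-QM bonded parameters whose terms cancel between the two MM
## calculations: all-QM terms surviving in the truncated topology (not the
## Q1-CL link bond, not cross-junction terms of a bonded CL pair)
eligible_dummy_params <- function(fx) {
  reg <- fx$region_map$region
  clcl <- fx$region_map$cl_cl_bonds
  spans <- function(v) {
    if (nrow(clcl) == 0) return(FALSE)
    any(vapply(seq_len(length(v) - 1), function(s)
      any((v[s] == clcl$i & v[s + 1] == clcl$j) |
          (v[s] == clcl$j & v[s + 1] == clcl$i)), logical(1)))
  }
  link_key <- paste(pmin(fx$link_specs$q1, fx$link_specs$cl),
                    pmax(fx$link_specs$q1, fx$link_specs$cl))
  out <- list()
  for (r in seq_len(nrow(fx$topology$bonds))) {
    v <- c(fx$topology$bonds$i[r], fx$topology$bonds$j[r])
    if (all(reg[v] == "QM") && !spans(v) &&
        !(paste(min(v), max(v)) %in% link_key))
      out[[length(out) + 1]] <- list(class = "bonds", row = r, par = "kb")
  }
  for (r in seq_len(nrow(fx$topology$angles))) {
    v <- unlist(fx$topology$angles[r, c("i", "j", "k")])
    if (all(reg[v] == "QM") && !spans(v))
      out[[length(out) + 1]] <- list(class = "angles", row = r, par = "kth")
  }
  for (r in seq_len(nrow(fx$topology$dihedrals))) {
    v <- unlist(fx$topology$dihedrals[r, c("i", "j", "k", "l")])
    if (all(reg[v] == "QM") && !spans(v))
      out[[length(out) + 1]] <- list(class = "dihedrals", row = r, par = "vn2")
  }
  out
}
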