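# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: Kabsch/screw fits for helix geometry, explicit
# rotation-matrix composition for the CSA forward model, flood fill on a
# doubled pitch axis for connected components.

# Kabsch rotation mapping point set P onto Q (rows = points)
kabsch_rotation <- function(P, Q) {
  Pc <- scale(P, scale = FALSE)
  Qc <- scale(Q, scale = FALSE)
  s <- svd(t(Pc) %*% Qc)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

# screw rotation angle (degrees) between consecutive residues' backbone
# triads (N, CA, C) of a helix model
screw_angles <- function(model) {
  co <- model$coords
  triad <- function(i) {
    m <- co[co$residue == i & co$atom %in% c("N", "CA", "C"), ]
    as.matrix(m[match(c("N", "CA", "C"), m$atom), c("x", "y", "z")])
  }
  n <- nchar(model$sequence)
  vapply(seq_len(n - 1), function(i) {
    R <- kabsch_rotation(triad(i), triad(i + 1))
    acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
  }, 0)
}

# brute-force static shift: build the full rotation composition
# numerically and contract the lab-frame tensor with the field vector
oracle_static_shift <- function(frame, tensor, tilt, pitch) {
  rot <- function(u, th) {
    u <- u / sqrt(sum(u^2)); th <- th * pi / 180
    K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  b <- pi / 180 * tensor$beta_nh
  e33 <- cos(b) * frame$nh_unit + sin(b) * frame$in_plane_perp
  e22 <- frame$plane_normal
  e11 <- c(e22[2] * e33[3] - e22[3] * e33[2],
           e22[3] * e33[1] - e22[1] * e33[3],
           e22[1] * e33[2] - e22[2] * e33[1])
  S_mol <- tensor$sigma11 * tcrossprod(e11) +
    tensor$sigma22 * tcrossprod(e22) + tensor$sigma33 * tcrossprod(e33)
  # rotate the molecule: pitch about the helix axis (z), then tilt the
  # axis away from the membrane normal (about the lab y axis)
  R <- rot(c(0, 1, 0), tilt) %*% rot(c(0, 0, 1), pitch)
  S_lab <- R %*% S_mol %*% t(R)
  z <- c(0, 0, 1)
  as.numeric(z %*% S_lab %*% z)
}

# flood fill connected components on a mask whose pitch (column) axis is
# made explicit by doubling, as an oracle for wrap-around labeling;
# returns the number of distinct components and their sizes
oracle_region_sizes <- function(mask) {
  nt <- nrow(mask); np <- ncol(mask)
  wide <- cbind(mask, mask)  # doubled pitch axis
  lab <- matrix(0L, nt, 2 * np)
  nxt <- 0L
  for (i in seq_len(nt)) for (j in seq_len(2 * np)) {
    if (wide[i, j] && lab[i, j] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(i, j)); lab[i, j] <- nxt
      while (length(queue) > 0) {
        c0 <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          r <- c0[1] + di; s <- c0[2] + dj
          if (r >= 1 && r <= nt && s >= 1 && s <= 2 * np &&
              wide[r, s] && lab[r, s] == 0L) {
            lab[r, s] <- nxt
            queue[[length(queue) + 1]] <- c(r, s)
          }
        }
      }
    }
  }
  # components equivalent under the pitch period are the same region
  ids <- matrix(0L, nt, np)
  merge_map <- list()
  for (i in seq_len(nt)) for (j in seq_len(np)) {
    a <- lab[i, j]; b <- lab[i, j + np]
    if (a > 0L) merge_map[[as.character(a)]] <-
        union(merge_map[[as.character(a)]], b)
  }
  # union-find over the doubled labels
  parent <- seq_len(nxt)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (a in names(merge_map)) for (b in merge_map[[a]]) {
    ra <- find(as.integer(a)); rb <- find(b)
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(nxt), find, 0L)
  left <- lab[, seq_len(np), drop = FALSE]
  sizes <- table(roots[left[left > 0L]])
  sort(as.integer(sizes), decreasing = TRUE)
}

# run-length oracle for helix segment calling
oracle_segments <- function(supporting, residues, min_run) {
  segs <- list()
  i <- 1
  while (i <= length(supporting)) {
    if (supporting[i]) {
      j <- i
      while (j < length(supporting) && supporting[j + 1]) j <- j + 1
      if (j - i + 1 >= min_run)
        segs[[length(segs) + 1]] <- c(residues[i], residues[j])
      i <- j + 1
    } else i <- i + 1
  }
  segs
}
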