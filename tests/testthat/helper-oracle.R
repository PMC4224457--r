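# Independent, vectorised R implementation of the local fragment search:
# scores every rotation x translation fully (no early termination, no
# running threshold) and keeps the top n_best. Used as the brute-force
# oracle that the pruned search must reproduce exactly.

# round half away from zero, as the compiled search does
lround <- function(x) as.integer(trunc(x + 0.5 * sign(x)))

oracle_search_local <- function(grid, target, center, radius,
                                rotations, n_best = 50) {
  d <- dim(grid$values)
  sp <- grid$spacing
  org <- grid$origin
  v <- grid$values
  ilo <- ceiling((center - radius - org) / sp)
  ihi <- floor((center + radius - org) / sp)
  nodes <- as.matrix(expand.grid(i = ilo[1]:ihi[1], j = ilo[2]:ihi[2],
                                 k = ilo[3]:ihi[3]))
  pos <- cbind(org[1] + nodes[, 1] * sp[1], org[2] + nodes[, 2] * sp[2],
               org[3] + nodes[, 3] * sp[3])
  keep <- rowSums(sweep(pos, 2, center)^2) <= radius^2
  nodes <- nodes[keep, , drop = FALSE]
  pos <- pos[keep, , drop = FALSE]
  nt <- nrow(nodes)
  lookup <- function(ii, jj, kk)
    v[cbind(ii %% d[1] + 1L, jj %% d[2] + 1L, kk %% d[3] + 1L)]
  first_cut <- grid$mean + grid$sigma
  n <- target$n
  rot_id <- integer(0); node_id <- integer(0); sc <- numeric(0)
  for (r in seq_along(rotations)) {
    R <- rotations[[r]]
    ho <- target$high %*% t(R)
    lo <- target$low %*% t(R)
    hoff <- cbind(lround(ho[, 1] / sp[1]), lround(ho[, 2] / sp[2]),
                  lround(ho[, 3] / sp[3]))
    loff <- cbind(lround(lo[, 1] / sp[1]), lround(lo[, 2] / sp[2]),
                  lround(lo[, 3] / sp[3]))
    alive <- which(lookup(nodes[, 1] + hoff[1, 1], nodes[, 2] + hoff[1, 2],
                          nodes[, 3] + hoff[1, 3]) >= first_cut)
    if (!length(alive)) next
    minh <- rep(Inf, length(alive)); maxl <- rep(-Inf, length(alive))
    for (p in seq_len(n)) {
      minh <- pmin(minh, lookup(nodes[alive, 1] + hoff[p, 1],
                                nodes[alive, 2] + hoff[p, 2],
                                nodes[alive, 3] + hoff[p, 3]))
      maxl <- pmax(maxl, lookup(nodes[alive, 1] + loff[p, 1],
                                nodes[alive, 2] + loff[p, 2],
                                nodes[alive, 3] + loff[p, 3]))
    }
    s <- minh - maxl
    ok <- s >= 0
    rot_id <- c(rot_id, rep(r, sum(ok)))
    node_id <- c(node_id, alive[ok])
    sc <- c(sc, s[ok])
  }
  if (!length(sc)) return(list())
  top <- head(order(-sc), n_best)   # stable: earliest scan order wins ties
  trans <- pos[node_id[top], , drop = FALSE]
  smean <- vapply(seq_along(top), function(q)
    score_mean(target, grid,
               placement(rotations[[rot_id[top[q]]]], trans[q, ]),
               interpolated = TRUE), numeric(1))
  keep <- smean > 0
  dctr <- sqrt(rowSums(sweep(trans, 2, center)^2))
  ord <- order(-smean, dctr, rot_id[top])
  ord <- ord[keep[ord]]
  lapply(ord, function(q) {
    pl <- placement(rotations[[rot_id[top[q]]]], trans[q, ],
                    score_minmax = sc[top[q]], score_mean = smean[q])
    pl$rot_index <- rot_id[top[q]]
    pl
  })
}
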