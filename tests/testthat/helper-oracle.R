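# Independent shortest-path oracle: the move graph is materialized edge by
# edge in R and solved with igraph::distances, exercising none of the
# package's accumulation code path.

oracle_travel_time <- function(speed_kmh, walking, dem, src_cells, cell,
                               connectivity = 8) {
  nr <- nrow(speed_kmh); nc <- ncol(speed_kmh)
  v_ms <- speed_kmh / 3.6
  tob <- function(s) exp(-3.5 * (abs(s + 0.05) - 0.05))
  moves <- rbind(expand.grid(dr = -1:1, dc = -1:1))
  moves <- moves[!(moves$dr == 0 & moves$dc == 0), ]
  if (connectivity == 16)
    moves <- rbind(moves,
                   data.frame(dr = c(-2, -2, -1, -1, 1, 1, 2, 2),
                              dc = c(-1, 1, -2, 2, -2, 2, -1, 1)))
  from <- integer(); to <- integer(); w <- numeric()
  idx <- function(r, c) (c - 1L) * nr + r
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (v_ms[r, c] <= 0) next
    for (m in seq_len(nrow(moves))) {
      r2 <- r + moves$dr[m]; c2 <- c + moves$dc[m]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (v_ms[r2, c2] <= 0) next
      d <- cell * sqrt(moves$dr[m]^2 + moves$dc[m]^2)
      s <- (dem[r2, c2] - dem[r, c]) / d
      va <- if (walking[r, c]) v_ms[r, c] * tob(s) else v_ms[r, c]
      vb <- if (walking[r2, c2]) v_ms[r2, c2] * tob(s) else v_ms[r2, c2]
      from <- c(from, idx(r, c)); to <- c(to, idx(r2, c2))
      w <- c(w, d * (0.5 / va + 0.5 / vb))
    }
  }
  gr <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
  gr <- igraph::add_vertices(gr, max(0, nr * nc - igraph::vcount(gr)))
  dm <- igraph::distances(gr, v = src_cells, mode = "out", weights = w)
  matrix(apply(dm, 2, min) / 60, nr, nc)
}

random_oracle_case <- function(seed) {
  set.seed(seed)
  nr <- sample(3:12, 1); nc <- sample(3:12, 1)
  kmh <- matrix(stats::runif(nr * nc, 0.5, 40), nr, nc)
  kmh[stats::runif(nr * nc) < 0.15] <- 0  # barriers
  walking <- matrix(stats::runif(nr * nc) < 0.5, nr, nc)
  dem <- matrix(stats::runif(nr * nc, 0, 25), nr, nc)
  ns <- sample(1:3, 1)
  ok <- which(kmh > 0)
  src <- sample(ok, min(ns, length(ok)))
  list(kmh = kmh, walking = walking, dem = dem, src = src,
       conn = sample(c(8, 16), 1))
}

compare_to_oracle <- function(case, cell = 30) {
  sr <- make_speed_surface(case$kmh, walking = case$walking, cell = cell)
  g <- sr$grid
  rows <- (case$src - 1L) %% g$n_rows + 1L
  cols <- (case$src - 1L) %/% g$n_rows + 1L
  reg <- registry_at_cells(g, rows, cols)
  got <- accumulate(sr, acc_raster(g, case$dem), reg,
                    connectivity = case$conn)
  want <- oracle_travel_time(case$kmh, case$walking, case$dem, case$src,
                             cell, case$conn)
  gotv <- got$values; gotv[is.na(gotv)] <- Inf
  max(abs(gotv - want) / pmax(want, 1e-12), na.rm = TRUE)
}
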