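# shared fixtures, all built in code

# plane elevation grid: z = z0 + gx * x + gy * y (gradients as fractions)
plane_grid <- function(nr = 11, nc = 11, res = 2, gx = 0, gy = 0,
                       z0 = 100) {
  g <- ysz_grid(matrix(0, nr, nc), res = res)
  cc <- grid_cell_centers(g)
  m <- matrix(NA_real_, nr, nc)
  m[cbind(cc$row, cc$col)] <- z0 + gx * cc$x + gy * cc$y
  ysz_grid(m, res = res)
}

# small fast field configuration for replicate studies
small_fields <- function(res = 4, width = 120, height = 120) {
  default_study_fields(width = width, height = height, res = res)
}

small_design <- function() sample_design(min_spacing_m = 10,
                                         edge_buffer_m = 5)

# per-cell brute-force reimplementation of the zone rules, used as the
# classification oracle
brute_force_classify <- function(rel_arr, level_pct = 10, sd_pct = 15,
                                 min_frac = 0.8) {
  nr <- dim(rel_arr)[1]; nc <- dim(rel_arr)[2]; ny <- dim(rel_arr)[3]
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      v <- rel_arr[i, j, ]
      v <- v[!is.na(v)]
      if (length(v) < max(2, ceiling(min_frac * ny))) next
      lev <- mean(v); st <- sd(v)
      out[i, j] <-
        if (st > sd_pct) 4 else if (lev < -level_pct) 1 else
          if (lev > level_pct) 3 else 2
    }
  }
  out
}

# replicate-study cache so the expensive 50-study batteries are generated
# once and shared between test files
.study_cache <- new.env(parent = emptyenv())

replicate_studies <- function(n = 50, profile = zone_effect_profile(),
                              tag = "default") {
  key <- paste0(tag, "_", n)
  if (is.null(.study_cache[[key]])) {
    .study_cache[[key]] <- lapply(seq_len(n), function(s) {
      suppressWarnings(generate_study(small_fields(),
                                      profile = profile,
                                      design = small_design(),
                                      seed = s))
    })
  }
  .study_cache[[key]]
}

# independent brute-force D8: per-cell neighbour scan for the receiver, then
# path-walking to count, for every cell, all cells whose flow passes through
# it (plus itself)
brute_force_d8 <- function(z, res) {
  nr <- nrow(z); nc <- ncol(z)
  drow <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  dcol <- c(0, 1, 1, 1, 0, -1, -1, -1)
  recv <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      best <- 0; best_id <- 0L
      for (k in 1:8) {
        ni <- i + drow[k]; nj <- j + dcol[k]
        if (ni < 1 || ni > nr || nj < 1 || nj > nc) next
        dd <- (z[i, j] - z[ni, nj]) /
          (res * if (drow[k] != 0 && dcol[k] != 0) sqrt(2) else 1)
        id <- (ni - 1L) * nc + nj
        if (dd > best + 1e-15 ||
            (dd > 0 && abs(dd - best) <= 1e-15 &&
             (best_id == 0L || id < best_id))) {
          best <- dd; best_id <- id
        }
      }
      recv[i, j] <- best_id
    }
  }
  acc <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ci <- i; cj <- j
      repeat {
        acc[ci, cj] <- acc[ci, cj] + 1
        r <- recv[ci, cj]
        if (r == 0L) break
        ci <- (r - 1L) %/% nc + 1L
        cj <- (r - 1L) %% nc + 1L
      }
    }
  }
  acc
}
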