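# internal helpers shared across modules

# Deterministic 31-bit seed derived from a master seed and a string label, so
# per-field streams are reproducible under field-list reordering. Plain
# polynomial rolling hash; all arithmetic kept below 2^53 before reduction.
derive_seed <- function(master, label) {
  stopifnot(length(master) == 1L, is.finite(master))
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(master) %% m
  for (code in utf8ToInt(as.character(label))) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# Mean filter over a square window (half-width `k` cells), NA-aware, edges
# renormalised by the number of in-window cells. Used to give latent zone
# surfaces their patch structure.
smooth_matrix <- function(m, k) {
  if (k < 1L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  val <- m; val[is.na(val)] <- 0
  cnt <- matrix(as.numeric(!is.na(m)), nr, nc)
  acc_v <- matrix(0, nr, nc); acc_n <- matrix(0, nr, nc)
  for (di in -k:k) {
    ri <- pmin(pmax(seq_len(nr) + di, 1L), nr)
    vr <- val[ri, , drop = FALSE]; cr <- cnt[ri, , drop = FALSE]
    for (dj in -k:k) {
      cj <- pmin(pmax(seq_len(nc) + dj, 1L), nc)
      acc_v <- acc_v + vr[, cj, drop = FALSE]
      acc_n <- acc_n + cr[, cj, drop = FALSE]
    }
  }
  out <- acc_v / acc_n
  out[acc_n == 0] <- NA_real_
  out
}

# rank -> (0,1) transform used to turn latent surfaces into quantile scores
rank_unit <- function(x) {
  r <- rank(x, ties.method = "first", na.last = "keep")
  (r - 0.5) / sum(!is.na(x))
}

stop_missing_input <- function(msg, stage) {
  cond <- structure(
    class = c("ysz_missing_input", "error", "condition"),
    list(message = paste0(msg, " (run the `", stage, "` stage first)"),
         call = NULL, stage = stage)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
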