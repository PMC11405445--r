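# Independent brute-force L1 oracle: an L1 optimum interpolates p points,
# so the minimum over all nonsingular p-row exact fits is the global minimum.
brute_force_l1 <- function(X, y) {
  n <- nrow(X); p <- ncol(X)
  best <- Inf
  cmb <- utils::combn(n, p)
  for (k in seq_len(ncol(cmb))) {
    idx <- cmb[, k]
    Xb <- X[idx, , drop = FALSE]
    if (abs(det(Xb)) < 1e-9) next
    b <- solve(Xb, y[idx])
    best <- min(best, sum(abs(y - X %*% b)))
  }
  best
}

# Minimal hand-built discharge records: diagnosis/procedure codes as lists,
# covariates defaulted to plausible values.
make_records <- function(dx, pr = NULL, los = 5, dialect = "ICD9", ...) {
  n <- length(dx)
  cap <- if (dialect == "ICD9") 25L else 30L
  if (is.null(pr)) pr <- rep(list(character(0)), n)
  dxm <- matrix("", n, cap, dimnames = list(NULL, paste0("DX", 1:cap)))
  prm <- matrix("", n, 10L, dimnames = list(NULL, paste0("PR", 1:10)))
  for (i in seq_len(n)) {
    if (length(dx[[i]])) dxm[i, seq_along(dx[[i]])] <- dx[[i]]
    if (length(pr[[i]])) prm[i, seq_along(pr[[i]])] <- pr[[i]]
  }
  extra <- list(...)
  out <- data.frame(record_id = sprintf("H%03d", seq_len(n)),
                    dialect = rep(dialect, n), stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(dxm, stringsAsFactors = FALSE),
               as.data.frame(prm, stringsAsFactors = FALSE))
  out$los <- rep_len(los, n)
  out$total_charges <- rep_len(10000, n)
  out$ccr <- rep_len(0.5, n)
  out$cost <- out$total_charges * out$ccr
  out$age <- rep_len(50, n)
  out$n_diagnoses <- vapply(dx, length, integer(1))
  out$n_procedures <- vapply(pr, length, integer(1))
  out$urban_teaching <- rep_len(0, n)
  out$small_bedsize <- rep_len(0, n)
  out$severity_index <- rep_len(2, n)
  out$mortality_risk_index <- rep_len(2, n)
  out$wage_index <- rep_len(1, n)
  for (nm in names(extra)) out[[nm]] <- rep_len(extra[[nm]], n)
  out
}

# Recompute the generating linear median index for generated records.
linear_index <- function(records, beta) {
  beta[["intercept"]] +
    beta[["los"]] * records$los +
    beta[["n_diagnoses"]] * records$n_diagnoses +
    beta[["n_procedures"]] * records$n_procedures +
    beta[["urban_teaching"]] * records$urban_teaching +
    beta[["small_bedsize"]] * records$small_bedsize +
    beta[["age"]] * records$age +
    beta[["severity_index"]] * records$severity_index +
    beta[["mortality_risk_index"]] * records$mortality_risk_index +
    beta[["wage_index"]] * records$wage_index
}
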