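# Independent oracles. These deliberately re-derive everything (scaling
# included) with their own code so they share no path with the package.

# One-component PLS1 by the classic NIPALS iteration.
nipals_pls1 <- function(X, y_num, scale_mode = c("unit_variance", "pareto",
                                                 "center", "none")) {
  scale_mode <- match.arg(scale_mode)
  mu <- apply(X, 2, mean)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0] <- 1
  div <- switch(scale_mode, none = rep(1, ncol(X)), center = rep(1, ncol(X)),
                pareto = sqrt(sdv), unit_variance = sdv)
  if (scale_mode == "none") mu <- rep(0, ncol(X))
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, div, "/")
  ybar <- mean(y_num)
  yc <- y_num - ybar
  u <- yc
  w <- rep(0, ncol(X))
  for (iter in 1:200) {
    w_new <- drop(t(Xs) %*% u)
    w_new <- w_new / sqrt(sum(w_new^2))
    t_sc <- drop(Xs %*% w_new)
    c_y <- sum(yc * t_sc) / sum(t_sc^2)
    u <- yc * c_y
    if (sqrt(sum((w_new - w)^2)) < 1e-13) { w <- w_new; break }
    w <- w_new
  }
  t_sc <- drop(Xs %*% w)
  c_y <- sum(yc * t_sc) / sum(t_sc^2)
  list(w = w, c = c_y, mu = mu, div = div, ybar = ybar,
       predict = function(Xn) {
         Xn <- sweep(sweep(Xn, 2, mu, "-"), 2, div, "/")
         drop(Xn %*% w) * c_y + ybar
       })
}

# Welch two-sample t-test from the textbook formulas.
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  t_stat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}

# Pooled two-sample t-test, closed form.
pooled_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t_stat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}
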