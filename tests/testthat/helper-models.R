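# shared builders for tiny models and simulated inputs

twoLVModel <- function() {
  list(blocks = list(blockSpec("X", "x", "reflective"),
                     blockSpec("Y", "y", "reflective")),
       inner = innerSpec(c("X", "Y"), list(c("X", "Y"))))
}

# well-separated three-LV reflective model plus simulated data
threeLVReflective <- function(n = 1000, seed = 99) {
  set.seed(seed)
  a <- rnorm(n)
  b <- 0.6 * a + sqrt(1 - 0.36) * rnorm(n)
  cc <- 0.5 * a + 0.4 * b + 0.5 * rnorm(n)
  mkblock <- function(lv, y, lambda = 0.95) {
    mvs <- paste0(tolower(lv), 1:3)
    X <- sapply(1:3, function(i) lambda * y + sqrt(1 - lambda^2) * rnorm(n))
    colnames(X) <- mvs
    list(block = blockSpec(lv, mvs, "reflective"), X = X)
  }
  ba <- mkblock("A", a); bb <- mkblock("B", b); bc <- mkblock("C", cc)
  list(data = cbind(ba$X, bb$X, bc$X),
       blocks = list(ba$block, bb$block, bc$block),
       inner = innerSpec(c("A", "B", "C"),
                         list(c("A", "B"), c("A", "C"), c("B", "C"))))
}

benchmarkBlocks <- function(spec) {
  lapply(spec@blocks, function(b) blockSpec(b$lvName, b$mvNames, b$mode))
}

# single-patient landmark set with a tilted frame and plausible anatomy
tiltedLandmarks <- function(theta = 0, shift = c(0, 0), pid = "p1") {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  pts <- list(
    Po = c(-38, 2), Or = c(42, 2), S = c(0, 0),
    A = c(62, -31), B = c(66, -78), Pog = c(68, -92), Me = c(62, -98),
    Cd = c(-12, -2.6), Cp = c(25, -9.8),
    U6mc = c(43, -45), L6mc = c(43, -57))
  rows <- lapply(names(pts), function(lm) {
    q <- drop(R %*% pts[[lm]]) + shift
    do.call(rbind, lapply(c("T0", "T1", "T2"), function(tp)
      data.frame(patient_id = pid, timepoint = tp, landmark = lm,
                 x_mm = q[1], y_mm = q[2])))
  })
  do.call(rbind, rows)
}
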