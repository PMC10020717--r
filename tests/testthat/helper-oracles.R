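# Independent brute-force oracles used by the tests (no shared code with
# the implementation).

# shoelace area, explicit loop
polygon_area_test <- function(xy) {
  n <- nrow(xy)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + xy[i, 1] * xy[j, 2] - xy[j, 1] * xy[i, 2]
  }
  abs(s) / 2
}

# triangle-soup surface area, explicit loop
stl_area_test <- function(stl) {
  v <- stl$vertices
  total <- 0
  for (i in seq(1, nrow(v), by = 3)) {
    a <- v[i + 1, ] - v[i, ]; b <- v[i + 2, ] - v[i, ]
    cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
    total <- total + sqrt(sum(cr^2)) / 2
  }
  total
}
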