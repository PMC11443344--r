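# small deterministic fixtures built in code

# a uniform-color image with a full-frame leaf mask
uniform_image <- function(r, g, b, gray = NULL, n = 16) {
  arr <- array(0L, c(n, n, 3))
  arr[, , 1] <- r; arr[, , 2] <- g; arr[, , 3] <- b
  gm <- matrix(as.integer(gray %||% round((r + g + b) / 3)), n, n)
  FluorescenceImage(arr, gm, id = "uniform")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# seeded random gray image (values 0..255) with an optional random mask
random_gray <- function(seed, n = 8, p_mask = 1) {
  set.seed(seed)
  g <- matrix(sample(0:255, n * n, replace = TRUE), n, n)
  mask <- matrix(stats::runif(n * n) <= p_mask, n, n)
  list(gray = g, mask = mask)
}

# the two worked-example test confusion matrices (rows actual, cols predicted)
bilstm_example_cm <- function() {
  matrix(c(8, 2, 0, 0,
           1, 11, 0, 0,
           0, 3, 9, 0,
           0, 0, 0, 10), 4, 4, byrow = TRUE,
         dimnames = list(actual = c("A", "B", "C", "D"),
                         predicted = c("A", "B", "C", "D")))
}

dbo_bilstm_example_cm <- function() {
  matrix(c(10, 0, 0, 0,
           0, 10, 2, 0,
           0, 0, 12, 0,
           0, 0, 0, 10), 4, 4, byrow = TRUE,
         dimnames = list(actual = c("A", "B", "C", "D"),
                         predicted = c("A", "B", "C", "D")))
}

reference_spearman_table <- function() {
  utils::read.csv(system.file("extdata", "reference_spearman.csv",
                              package = "fluorChill"),
                  stringsAsFactors = FALSE)
}
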