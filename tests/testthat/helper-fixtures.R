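# Programmatic fixtures shared across test files.

solid_image <- function(r, g, b, size = 64, id = "solid") {
  px <- array(0, dim = c(size, size, 3))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  scene_image(px, id)
}

half_bw_image <- function(size = 350) {
  px <- array(0, dim = c(size, size, 3))
  px[, (size %/% 2 + 1):size, ] <- 255
  scene_image(px, "half_bw")
}

checker_image <- function(cell, size = 352) {
  m <- (outer(0:(size - 1) %/% cell, 0:(size - 1) %/% cell, "+") %% 2) * 255
  scene_image(array(rep(m, 3), dim = c(size, size, 3)),
              paste0("checker", cell))
}

grating_image <- function(freq, phi, n = 256) {
  xg <- matrix(rep(0:(n - 1), each = n), n, n) # column (x) index
  yg <- matrix(rep(0:(n - 1), times = n), n, n)
  m <- 127.5 + 127.5 * cos(2 * pi * freq * (xg * cos(phi) + yg * sin(phi)))
  scene_image(array(rep(m, 3), dim = c(n, n, 3)), sprintf("grating%.2f", phi))
}

# Small embedding table with hand-picked geometry.
toy_embeddings <- function() {
  embedding_table(rbind(
    dog = c(1, 0, 0),
    puppy = c(1, 0, 0),      # identical to dog
    cat = c(0, 1, 0),        # orthogonal to dog
    anticat = c(0, -1, 0),   # opposite of cat
    mix = c(1, 1, 0) / sqrt(2)
  ))
}

# Response table from a per-image vector of "closer" counts out of n each.
response_table <- function(n_closer, n_total) {
  ids <- sprintf("img%02d", seq_along(n_closer))
  pids <- sprintf("p%03d", seq_len(n_total))
  do.call(rbind, lapply(seq_along(ids), function(i) {
    data.frame(participant_id = pids, image_id = ids[i],
               response = rep(c("closer", "farther"),
                              c(n_closer[i], n_total - n_closer[i])),
               stringsAsFactors = FALSE)
  }))
}
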