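# GIF89a writer for snapshot animations. No GIF encoder exists in the
# installed R stack, so frames are quantized to a fixed 6x6x6 color cube
# and the LZW stream is emitted as literal codes with periodic clear
# codes (fixed 9-bit code width), which every decoder accepts.

u16le <- function(x) as.raw(c(x %% 256L, x %/% 256L))

gif_palette <- function() {
  lv <- as.integer(round(seq(0, 255, length.out = 6)))
  cube <- expand.grid(b = lv, g = lv, r = lv)[, c("r", "g", "b")]
  pal <- rbind(as.matrix(cube), matrix(0L, 256 - 216, 3))
  as.raw(t(pal))
}

quantize_frame <- function(frame) {
  # frame: H x W x 3 in [0,1] -> palette indices, row-major (GIF raster order)
  q <- function(ch) as.integer(round(pmin(pmax(frame[, , ch], 0), 1) * 5))
  idx <- q(1) * 36L + q(2) * 6L + q(3)
  as.integer(t(matrix(idx, dim(frame)[1], dim(frame)[2])))
}

lzw_literal_stream <- function(indices) {
  clear <- 256L
  eoi <- 257L
  # After a clear, a decoder accepts 254 literal 9-bit codes before the
  # table would outgrow 9 bits; re-clear before that happens.
  chunks <- split(indices, (seq_along(indices) - 1L) %/% 254L)
  codes <- c(unlist(lapply(chunks, function(ch) c(clear, ch)),
                    use.names = FALSE), eoi)
  bits <- matrix(FALSE, 9L, length(codes))
  for (b in 0:8) bits[b + 1L, ] <- bitwAnd(codes, bitwShiftL(1L, b)) > 0L
  stream <- as.vector(bits)
  pad <- (-length(stream)) %% 8L
  packBits(c(stream, rep(FALSE, pad)), "raw")
}

sub_blocks <- function(bytes) {
  starts <- seq(1L, length(bytes), by = 255L)
  out <- lapply(starts, function(s) {
    chunk <- bytes[s:min(s + 254L, length(bytes))]
    c(as.raw(length(chunk)), chunk)
  })
  c(do.call(c, out), as.raw(0L))
}

#' Write frames as an animated GIF
#'
#' Encodes a list of RGB frames (as produced by [animate()]) into a
#' looping GIF89a file with a shared 216-color palette.
#'
#' @param frames List of `height x width x 3` arrays in `[0, 1]`, all of
#'   one size (e.g. a `qc_animation`).
#' @param path Output file.
#' @param delay_cs Inter-frame delay in hundredths of a second.
#' @return `path`, invisibly.
#' @export
write_gif <- function(frames, path, delay_cs = 10) {
  stopifnot(length(frames) >= 1)
  dims <- dim(frames[[1]])
  h <- dims[1]
  w <- dims[2]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("GIF89a"), con)
  writeBin(c(u16le(w), u16le(h), as.raw(c(0xF7, 0, 0))), con)
  writeBin(gif_palette(), con)
  # NETSCAPE looping extension
  writeBin(c(as.raw(c(0x21, 0xFF, 0x0B)), charToRaw("NETSCAPE2.0"),
             as.raw(c(0x03, 0x01, 0x00, 0x00, 0x00))), con)
  for (frame in frames) {
    stopifnot(identical(dim(frame)[1:2], dims[1:2]))
    writeBin(c(as.raw(c(0x21, 0xF9, 0x04, 0x00)), u16le(delay_cs),
               as.raw(c(0x00, 0x00))), con)
    writeBin(c(as.raw(0x2C), u16le(0), u16le(0), u16le(w), u16le(h),
               as.raw(0x00)), con)
    writeBin(as.raw(0x08), con)  # LZW minimum code size
    writeBin(sub_blocks(lzw_literal_stream(quantize_frame(frame))), con)
  }
  writeBin(as.raw(0x3B), con)
  invisible(path)
}

# Frame count of a GIF file (counts image descriptors); used to verify
# written animations without an external decoder.
gif_frame_count <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  stopifnot(identical(rawToChar(bytes[1:6]), "GIF89a"))
  pos <- 14L + 3L * 256L  # header + screen descriptor + global color table
  frames <- 0L
  n <- length(bytes)
  skip_blocks <- function(p) {
    repeat {
      len <- as.integer(bytes[p])
      p <- p + 1L
      if (len == 0L) return(p)
      p <- p + len
    }
  }
  while (pos <= n) {
    marker <- as.integer(bytes[pos])
    if (marker == 0x3B) break
    if (marker == 0x21) {
      pos <- skip_blocks(pos + 2L)
    } else if (marker == 0x2C) {
      frames <- frames + 1L
      packed <- as.integer(bytes[pos + 9L])
      pos <- pos + 10L
      if (bitwAnd(packed, 0x80L) > 0L) {
        pos <- pos + 3L * 2L^(bitwAnd(packed, 0x07L) + 1L)
      }
      pos <- skip_blocks(pos + 1L)
    } else {
      abort(sprintf("unexpected GIF block marker 0x%02X at offset %d", marker, pos))
    }
  }
  frames
}
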