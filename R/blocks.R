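#' Blocks needed to book a duration
#'
#' Completion times live on the block grid: a duration is rounded **up** to
#' the nearest whole block, `ceiling(dos / block_minutes)`.
#'
#' @param dos duration(s) of surgery in minutes, each > 0.
#' @param block_minutes grid quantum in minutes.
#' @return integer block count(s).
#' @examples
#' blocks_required(72, 10)  # 8
#' blocks_required(61, 15)  # 5
#' @export
blocks_required <- function(dos, block_minutes) {
  if (!is.numeric(dos) || any(is.na(dos)) || any(dos <= 0))
    stop("`dos` must be positive minutes", call. = FALSE)
  block_minutes <- assert_count(block_minutes, "block_minutes")
  as.integer(ceiling(dos / block_minutes))
}
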