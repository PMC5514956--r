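// Minimal 16-bit grayscale PNG writer (no installed R package can write
// 16-bit PNG; reading goes through png::readPNG, which supports it).
// Stream layout: signature, IHDR (bit depth 16, color type 0), one IDAT
// with a zlib-compressed image (filter byte 0 per scanline, big-endian
// samples), IEND.  CRC and compression come from zlib.

#include <Rcpp.h>
#include <zlib.h>
#include <cstring>

static void push_be32(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back((x >> 24) & 0xff); v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);  v.push_back(x & 0xff);
}

static void push_chunk(std::vector<unsigned char>& out, const char* type,
                       const std::vector<unsigned char>& data) {
  push_be32(out, (uint32_t)data.size());
  size_t start = out.size();
  out.insert(out.end(), type, type + 4);
  out.insert(out.end(), data.begin(), data.end());
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, out.data() + start, (uInt)(out.size() - start));
  push_be32(out, (uint32_t)crc);
}

// [[Rcpp::export]]
void write_png16_cpp(Rcpp::IntegerMatrix img, std::string path) {
  const int h = img.nrow(), w = img.ncol();
  std::vector<unsigned char> raw((size_t)h * (2 * w + 1));
  size_t pos = 0;
  for (int i = 0; i < h; ++i) {
    raw[pos++] = 0;                       // filter: none
    for (int j = 0; j < w; ++j) {
      int v = img(i, j);
      if (v < 0) v = 0;
      if (v > 65535) v = 65535;
      raw[pos++] = (unsigned char)((v >> 8) & 0xff);
      raw[pos++] = (unsigned char)(v & 0xff);
    }
  }
  uLongf zlen = compressBound((uLong)raw.size());
  std::vector<unsigned char> z(zlen);
  if (compress2(z.data(), &zlen, raw.data(), (uLong)raw.size(), 9) != Z_OK) {
    Rcpp::stop("zlib compression failed");
  }
  z.resize(zlen);

  std::vector<unsigned char> out;
  const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  out.insert(out.end(), sig, sig + 8);
  std::vector<unsigned char> ihdr;
  push_be32(ihdr, (uint32_t)w);
  push_be32(ihdr, (uint32_t)h);
  ihdr.push_back(16);  // bit depth
  ihdr.push_back(0);   // grayscale
  ihdr.push_back(0); ihdr.push_back(0); ihdr.push_back(0);
  push_chunk(out, "IHDR", ihdr);
  push_chunk(out, "IDAT", z);
  push_chunk(out, "IEND", std::vector<unsigned char>());

  FILE* f = std::fopen(path.c_str(), "wb");
  if (!f) Rcpp::stop("cannot open file for writing: %s", path);
  std::fwrite(out.data(), 1, out.size(), f);
  std::fclose(f);
}
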