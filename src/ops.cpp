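#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Tensors are numeric 3-d arrays in R layout (H, W, C), column-major.
// Conv weights are 4-d arrays (kh, kw, cin_per_group, cout).

// [[Rcpp::export]]
NumericVector conv2d_hwc(NumericVector x, NumericVector w, NumericVector bias,
                         int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int kh = wd[0], kw = wd[1], cpg = wd[2], CO = wd[3];
  if (C % groups != 0 || CO % groups != 0)
    stop("groups must divide channel counts");
  if (C / groups != cpg) stop("weight/input channel mismatch");
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector out(Ho * Wo * CO);
  out.attr("dim") = IntegerVector::create(Ho, Wo, CO);
  const double *px = x.begin();
  const double *pw = w.begin();
  double *po = out.begin();
  const bool has_bias = bias.size() == CO;
  const int co_per_g = CO / groups;
  for (int oc = 0; oc < CO; ++oc) {
    const int g = oc / co_per_g;
    const double b0 = has_bias ? bias[oc] : 0.0;
    for (int ow = 0; ow < Wo; ++ow) {
      const int iw0 = ow * stride - pad;
      for (int oh = 0; oh < Ho; ++oh) {
        const int ih0 = oh * stride - pad;
        double acc = b0;
        for (int ic = 0; ic < cpg; ++ic) {
          const int c_in = g * cpg + ic;
          const double *xc = px + (size_t)c_in * H * W;
          const double *wc = pw + ((size_t)oc * cpg + ic) * kh * kw;
          for (int v = 0; v < kw; ++v) {
            const int iw = iw0 + v;
            if (iw < 0 || iw >= W) continue;
            const double *xcol = xc + (size_t)iw * H;
            const double *wcol = wc + (size_t)v * kh;
            for (int u = 0; u < kh; ++u) {
              const int ih = ih0 + u;
              if (ih < 0 || ih >= H) continue;
              acc += xcol[ih] * wcol[u];
            }
          }
        }
        po[(size_t)oc * Ho * Wo + (size_t)ow * Ho + oh] = acc;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector pool2d_hwc(NumericVector x, int kernel, int stride, int pad,
                         bool max_pool) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int Ho = (H + 2 * pad - kernel) / stride + 1;
  const int Wo = (W + 2 * pad - kernel) / stride + 1;
  NumericVector out(Ho * Wo * C);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  const double *px = x.begin();
  double *po = out.begin();
  for (int c = 0; c < C; ++c) {
    const double *xc = px + (size_t)c * H * W;
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        double acc = max_pool ? R_NegInf : 0.0;
        int n = 0;
        for (int v = 0; v < kernel; ++v) {
          const int iw = ow * stride - pad + v;
          if (iw < 0 || iw >= W) continue;
          for (int u = 0; u < kernel; ++u) {
            const int ih = oh * stride - pad + u;
            if (ih < 0 || ih >= H) continue;
            const double val = xc[(size_t)iw * H + ih];
            if (max_pool) { if (val > acc) acc = val; }
            else acc += val;
            ++n;
          }
        }
        // average pools use the fixed 1/k^2 kernel (zero padding counted),
        // matching the affine average-pool prior
        po[(size_t)c * Ho * Wo + (size_t)ow * Ho + oh] =
            max_pool ? acc : acc / (kernel * kernel);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector upsample_nearest_hwc(NumericVector x, int factor) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int Ho = H * factor, Wo = W * factor;
  NumericVector out(Ho * Wo * C);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  const double *px = x.begin();
  double *po = out.begin();
  for (int c = 0; c < C; ++c)
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh)
        po[(size_t)c * Ho * Wo + (size_t)ow * Ho + oh] =
            px[(size_t)c * H * W + (size_t)(ow / factor) * H + oh / factor];
  return out;
}

static inline uint16_t float_to_half(float f) {
  uint32_t x;
  std::memcpy(&x, &f, 4);
  uint32_t sign = (x >> 16) & 0x8000u;
  int32_t exp = ((x >> 23) & 0xFF) - 127 + 15;
  uint32_t mant = x & 0x7FFFFFu;
  if (exp <= 0) {
    if (exp < -10) return (uint16_t)sign;            // underflow to 0
    mant |= 0x800000u;
    uint32_t shift = 14 - exp;
    return (uint16_t)(sign | (mant >> shift));
  }
  if (exp >= 31) return (uint16_t)(sign | 0x7C00u);  // overflow to inf
  return (uint16_t)(sign | (exp << 10) | (mant >> 13));
}

static inline float half_to_float(uint16_t h) {
  uint32_t sign = (uint32_t)(h & 0x8000u) << 16;
  uint32_t exp = (h >> 10) & 0x1F;
  uint32_t mant = h & 0x3FFu;
  uint32_t x;
  if (exp == 0) {
    if (mant == 0) x = sign;
    else {
      int e = -1;
      do { ++e; mant <<= 1; } while (!(mant & 0x400u));
      x = sign | ((uint32_t)(127 - 15 - e) << 23) | ((mant & 0x3FFu) << 13);
    }
  } else if (exp == 31) {
    x = sign | 0x7F800000u | (mant << 13);
  } else {
    x = sign | ((exp - 15 + 127) << 23) | (mant << 13);
  }
  float f;
  std::memcpy(&f, &x, 4);
  return f;
}

// [[Rcpp::export]]
RawVector pack_fp16(NumericVector x) {
  RawVector out(x.size() * 2);
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    uint16_t h = float_to_half((float)x[i]);
    out[2 * i] = (Rbyte)(h & 0xFF);
    out[2 * i + 1] = (Rbyte)(h >> 8);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector unpack_fp16(RawVector r) {
  NumericVector out(r.size() / 2);
  for (R_xlen_t i = 0; i < out.size(); ++i) {
    uint16_t h = (uint16_t)r[2 * i] | ((uint16_t)r[2 * i + 1] << 8);
    out[i] = half_to_float(h);
  }
  return out;
}
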