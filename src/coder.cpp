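// Adaptive context-mixing coder for nucleotide payloads.
//
// Alphabet: A,C,G,T,N -> 0..4.  The model mixes two kinds of experts:
//
//   * one count table per context order j = 0..k (k = context_order),
//     each predicting with the smoothed estimator
//     p_j(s) = (c_j(s) + 1/8) / (T_j + 5/8);
//   * a match expert that tracks a repeated (or homologous) region of
//     the history: it anchors on the most recent exact occurrence of the
//     current 16-mer suffix (via a rolling-hash position table), then
//     predicts the symbol that followed the anchored position with an
//     adaptively estimated hit probability q (decayed success/failure
//     counts), spreading 1 - q over the other symbols in proportion to
//     the context experts\' own prediction.  Because the
//     pointer keeps advancing through mismatches, the expert keeps
//     tracking a homolog whose similarity is well below what exact
//     k-mer statistics can exploit, and q converges to the local
//     sequence identity; the match is abandoned when q drops to the
//     random-background level and re-anchored whenever a better exact
//     seed appears.
//
// The experts form a mixture of specialists: an expert without a
// prediction (empty context / no active match) abstains, the active ones
// contribute p(s) = sum_j w_j p_j(s) with weights renormalized over the
// active set, and after every symbol each active expert's weight is
// scaled by p_j(s) / p(s) -- its predictive success relative to the
// mixture -- while abstainers keep their weight.  Weights are mixed with
// a small uniform fraction (1/64) each step so the model can re-weight
// when the statistics drift.  The mixture is quantized to a 14-bit total (every
// symbol kept >= 1; encoder and decoder quantize identically, so coding
// stays lossless) and driven through classic 32-bit arithmetic coding
// with underflow (pending-bit) handling.  Counts in a context are halved
// once their sum reaches 16000.
//
// The initial context is the all-A history; conditional coding primes
// the count tables with a full pass over the conditioning payload and
// then restarts from the initial context.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

const uint64_t TOPV = 0xFFFFFFFFULL;
const uint64_t HALF = 0x80000000ULL;
const uint64_t QTR = 0x40000000ULL;
const uint64_t QTR3 = 0xC0000000ULL;
const uint64_t RESCALE_AT = 16000;
const uint64_t QTOT = 1u << 14;  // quantized frequency total
const double PC = 0.125;         // per-symbol pseudocount of each order
const double WMIX = 1.0 / 64.0;  // uniform fraction of the weight update
const int MINLEN = 10;           // exact seed length of the match expert
const double MDECAY = 0.98;      // decay of the match hit/miss counts
const size_t MHBITS = 20;        // log2 size of the seed position table

inline int sym_of(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    case 'N': return 4;
    default:
      stop("payload contains a character outside {A,C,G,T,N}: '%s'",
           std::string(1, c).c_str());
  }
  return -1;  // unreached
}

struct BitSink {
  std::vector<uint8_t>* out;  // NULL: count bits only
  uint64_t nbits;
  uint8_t cur;
  int fill;
  explicit BitSink(std::vector<uint8_t>* buf)
      : out(buf), nbits(0), cur(0), fill(0) {}
  void put(int bit) {
    ++nbits;
    if (out) {
      cur = static_cast<uint8_t>((cur << 1) | bit);
      if (++fill == 8) {
        out->push_back(cur);
        cur = 0;
        fill = 0;
      }
    }
  }
  void flush() {
    if (out && fill > 0) {
      out->push_back(static_cast<uint8_t>(cur << (8 - fill)));
      cur = 0;
      fill = 0;
    }
  }
};

struct BitSource {
  const uint8_t* data;
  size_t n, pos;
  int fill;
  uint8_t cur;
  uint64_t overrun;
  BitSource(const uint8_t* d, size_t len)
      : data(d), n(len), pos(0), fill(0), cur(0), overrun(0) {}
  int get() {
    if (fill == 0) {
      if (pos < n) {
        cur = data[pos++];
      } else {
        cur = 0;
        ++overrun;
      }
      fill = 8;
    }
    --fill;
    return (cur >> fill) & 1;
  }
};

struct Model {
  int order;
  std::vector<std::vector<uint32_t>> counts;  // one table per order 0..k
  std::vector<uint64_t> ctx, nctx;            // rolling context per order
  std::vector<double> w;                      // weights: orders 0..k, match
  // match expert state
  std::vector<uint8_t> hist;                  // all symbols seen so far
  std::vector<uint32_t> mhash;                // seed hash -> position + 1
  uint64_t rhash;                             // rolling hash of the suffix
  uint64_t rh_out;                            // 5^MINLEN, outgoing factor
  size_t mptr;                                // next predicted position
  bool mvalid;
  double ma, mb;                              // decayed hits / misses

  explicit Model(int k) : order(k) {
    if (k < 1 || k > 8) stop("context_order must be between 1 and 8");
    counts.resize(k + 1);
    ctx.assign(k + 1, 0);
    nctx.assign(k + 1, 1);
    w.assign(k + 2, 1.0 / (k + 2));
    for (int j = 0; j <= k; ++j) {
      if (j > 0) nctx[j] = nctx[j - 1] * 5;
      counts[j].assign(nctx[j] * 5, 0u);
    }
    mhash.assign(size_t(1) << MHBITS, 0u);
    rhash = 0;
    rh_out = 1;
    for (int i = 0; i < MINLEN; ++i) rh_out *= 5;
    mptr = 0;
    mvalid = false;
    ma = mb = 0;
  }

  void reset_context() {
    std::fill(ctx.begin(), ctx.end(), 0);
    mvalid = false;
    ma = mb = 0;
  }

  bool match_active() const { return mvalid && mptr < hist.size(); }
  double match_q() const {
    double q = (ma + 0.5) / (ma + mb + 1.0);
    if (q < 0.05) q = 0.05;
    if (q > 0.99) q = 0.99;
    return q;
  }

  // mixture over active experts; fills the final distribution p[5] and,
  // when the match expert is active, its own distribution pmatch[5]
  // (q on the predicted symbol, 1 - q spread over the rest according to
  // the context experts)
  void mixture(double p[5], double pmatch[5]) const {
    double pctx[5] = {0, 0, 0, 0, 0};
    double norm = 0;
    for (int j = 0; j <= order; ++j) {
      const uint32_t* c = &counts[j][ctx[j] * 5];
      double tot = (double)c[0] + c[1] + c[2] + c[3] + c[4];
      if (j > 0 && tot == 0) continue;  // abstain on an empty context
      norm += w[j];
      double inv = w[j] / (tot + 5 * PC);
      for (int s = 0; s < 5; ++s) pctx[s] += inv * (c[s] + PC);
    }
    for (int s = 0; s < 5; ++s) pctx[s] /= norm;  // context-only mixture
    if (match_active()) {
      double q = match_q();
      int pred = hist[mptr];
      double rest = 1.0 - pctx[pred];
      for (int s = 0; s < 5; ++s)
        pmatch[s] = (s == pred) ? q : (1.0 - q) * pctx[s] / rest;
      double wm = w[order + 1] / (norm + w[order + 1]);
      for (int s = 0; s < 5; ++s)
        p[s] = (1.0 - wm) * pctx[s] + wm * pmatch[s];
    } else {
      for (int s = 0; s < 5; ++s) p[s] = pctx[s];
    }
  }

  // mixture distribution, quantized to integer frequencies summing ~QTOT
  void cumfreqs(uint64_t cum[6]) const {
    double p[5], pm[5];
    mixture(p, pm);
    cum[0] = 0;
    for (int s = 0; s < 5; ++s) {
      uint64_t f = (uint64_t)(p[s] * (double)(QTOT - 5) + 0.5);
      if (f < 1) f = 1;
      cum[s + 1] = cum[s] + f;
    }
  }

  size_t seed_slot() const {
    return (rhash * 0x9E3779B97F4A7C15ull) >> (64 - MHBITS);
  }
  // verify that the seed ending at stored position matches our suffix
  bool seed_matches(size_t cand) const {
    size_t t = hist.size();
    if (cand < (size_t)MINLEN || cand > t) return false;
    for (int i = 1; i <= MINLEN; ++i)
      if (hist[cand - i] != hist[t - i]) return false;
    return true;
  }

  void update(int s) {
    // relative reweighting of the active experts by predictive success
    double p[5], pmt[5];
    mixture(p, pmt);
    double pmix = p[s];
    for (int j = 0; j <= order; ++j) {
      const uint32_t* c = &counts[j][ctx[j] * 5];
      double tot = (double)c[0] + c[1] + c[2] + c[3] + c[4];
      if (j > 0 && tot == 0) continue;
      w[j] *= ((c[s] + PC) / (tot + 5 * PC)) / pmix;
    }
    bool was_active = match_active();
    if (was_active) w[order + 1] *= pmt[s] / pmix;
    double tot_w = 0;
    for (size_t j = 0; j < w.size(); ++j) tot_w += w[j];
    double u = WMIX / w.size();
    for (size_t j = 0; j < w.size(); ++j)
      w[j] = (1.0 - WMIX) * (w[j] / tot_w) + u;

    // match bookkeeping: score the prediction, advance the pointer,
    // abandon a match that has degraded to the random background
    if (was_active) {
      if (hist[mptr] == s) {
        ma = ma * MDECAY + 1;
        mb = mb * MDECAY;
      } else {
        ma = ma * MDECAY;
        mb = mb * MDECAY + 1;
      }
      ++mptr;
      if (ma + mb > 30 && match_q() < 0.28) mvalid = false;
    }

    // extend the history and the rolling seed hash
    hist.push_back((uint8_t)s);
    size_t t = hist.size();
    rhash = rhash * 5 + (uint64_t)s;
    if (t > (size_t)MINLEN) rhash -= rh_out * (uint64_t)hist[t - MINLEN - 1];
    if (t >= (size_t)MINLEN) {
      size_t slot = seed_slot();
      // re-anchor on a fresh exact seed once the current match is gone
      // (a live match is never hijacked: at high divergence its hit rate
      // sits near 1/2 and a "better" random seed would usually be worse)
      if (!match_active()) {
        size_t cand = mhash[slot];
        if (cand > 0 && cand < t && seed_matches(cand)) {
          mptr = cand;
          mvalid = true;
          ma = 1;
          mb = 0;
        }
      }
      mhash[slot] = (uint32_t)t;
    }

    // count update and context advance
    for (int j = 0; j <= order; ++j) {
      uint32_t* c = &counts[j][ctx[j] * 5];
      uint64_t tot = (uint64_t)c[0] + c[1] + c[2] + c[3] + c[4];
      if (tot >= RESCALE_AT)
        for (int i = 0; i < 5; ++i) c[i] >>= 1;
      c[s] += 1;
      if (j > 0) ctx[j] = (ctx[j] % (nctx[j] / 5)) * 5 + (uint64_t)s;
    }
  }
};

struct Encoder {
  uint64_t low, high;
  uint64_t pending;
  BitSink* sink;
  explicit Encoder(BitSink* s) : low(0), high(TOPV), pending(0), sink(s) {}
  void emit(int b) {
    sink->put(b);
    while (pending) {
      sink->put(!b);
      --pending;
    }
  }
  void encode(uint64_t cumlo, uint64_t cumhi, uint64_t tot) {
    uint64_t range = high - low + 1;
    high = low + range * cumhi / tot - 1;
    low = low + range * cumlo / tot;
    for (;;) {
      if (high < HALF) {
        emit(0);
      } else if (low >= HALF) {
        emit(1);
        low -= HALF;
        high -= HALF;
      } else if (low >= QTR && high < QTR3) {
        ++pending;
        low -= QTR;
        high -= QTR;
      } else {
        break;
      }
      low <<= 1;
      high = (high << 1) | 1;
    }
  }
  void finish() {
    ++pending;
    if (low < QTR)
      emit(0);
    else
      emit(1);
  }
};

// encode payload symbols through a (possibly primed) model; bits counted
// or written depending on the sink
void encode_payload(const std::string& x, Model& model, BitSink& sink) {
  if (x.empty()) return;
  Encoder enc(&sink);
  uint64_t cum[6];
  for (size_t i = 0; i < x.size(); ++i) {
    int s = sym_of(x[i]);
    model.cumfreqs(cum);
    enc.encode(cum[s], cum[s + 1], cum[5]);
    model.update(s);
  }
  enc.finish();
  // 32 padding bits so a decoder never has to read past the end of a
  // valid stream; any overrun therefore proves truncation/corruption
  for (int i = 0; i < 32; ++i) sink.put(0);
  sink.flush();
}

void prime_model(const std::string& y, Model& model) {
  for (size_t i = 0; i < y.size(); ++i) model.update(sym_of(y[i]));
  model.reset_context();
}

}  // namespace

// [[Rcpp::export(name = ".cg_encode")]]
RawVector cg_encode(std::string x, int order) {
  std::vector<uint8_t> buf;
  // 8-byte big-endian symbol count header
  uint64_t n = x.size();
  for (int i = 7; i >= 0; --i) buf.push_back((n >> (8 * i)) & 0xFF);
  Model model(order);
  BitSink sink(&buf);
  encode_payload(x, model, sink);
  RawVector out(buf.size());
  std::copy(buf.begin(), buf.end(), out.begin());
  return out;
}

// [[Rcpp::export(name = ".cg_decode")]]
std::string cg_decode(RawVector stream, int order) {
  if (stream.size() < 8)
    stop("corrupt bitstream: shorter than the 8-byte header");
  const uint8_t* raw = reinterpret_cast<const uint8_t*>(RAW(stream));
  uint64_t n = 0;
  for (int i = 0; i < 8; ++i) n = (n << 8) | raw[i];
  if (n > (1ull << 40)) stop("corrupt bitstream: implausible symbol count");
  std::string out;
  out.reserve(n);
  if (n == 0) {
    if (stream.size() != 8)
      stop("corrupt bitstream: trailing bytes after an empty payload");
    return out;
  }
  Model model(order);
  BitSource src(raw + 8, static_cast<size_t>(stream.size()) - 8);
  uint64_t low = 0, high = TOPV, value = 0;
  for (int i = 0; i < 32; ++i) value = (value << 1) | src.get();
  static const char ALPHA[5] = {'A', 'C', 'G', 'T', 'N'};
  uint64_t cum[6];
  for (uint64_t i = 0; i < n; ++i) {
    model.cumfreqs(cum);
    uint64_t tot = cum[5];
    uint64_t range = high - low + 1;
    uint64_t off = ((value - low + 1) * tot - 1) / range;
    int s = 0;
    while (cum[s + 1] <= off) ++s;
    high = low + range * cum[s + 1] / tot - 1;
    low = low + range * cum[s] / tot;
    for (;;) {
      if (high < HALF) {
        // nothing
      } else if (low >= HALF) {
        low -= HALF;
        high -= HALF;
        value -= HALF;
      } else if (low >= QTR && high < QTR3) {
        low -= QTR;
        high -= QTR;
        value -= QTR;
      } else {
        break;
      }
      low <<= 1;
      high = (high << 1) | 1;
      value = (value << 1) | src.get();
    }
    out.push_back(ALPHA[s]);
    model.update(s);
    // the encoder pads 32 bits, covering the decoder pre-read: a valid
    // stream is never read past its end
    if (src.overrun > 0) stop("corrupt or truncated bitstream");
  }
  uint64_t remaining = (src.n - src.pos) * 8 + src.fill;
  if (remaining > 64) stop("corrupt bitstream: trailing bytes");
  return out;
}

// [[Rcpp::export(name = ".cg_size_bits")]]
double cg_size_bits(std::string x, int order) {
  Model model(order);
  BitSink sink(nullptr);
  encode_payload(x, model, sink);
  return static_cast<double>(sink.nbits);
}

// [[Rcpp::export(name = ".cg_cond_size_bits")]]
double cg_cond_size_bits(std::string x, std::string y, int order) {
  Model model(order);
  prime_model(y, model);
  BitSink sink(nullptr);
  encode_payload(x, model, sink);
  return static_cast<double>(sink.nbits);
}
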