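// Exact sparse multivariate polynomial arithmetic over Q.
//
// A polynomial is passed from R as list(E = integer matrix (terms x nvars),
// num = numeric, den = numeric) with coefficients num/den exact integers
// (|.| < 2^53 so doubles represent them exactly).  All variables live in a
// fixed symbol table managed on the R side; E always has the full width.
// Internally coefficients are long long rationals reduced by gcd; products
// go through __int128 and overflow past 2^62 throws, so a wrong answer can
// never be returned silently.

#include <Rcpp.h>
#include <map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

typedef std::vector<int> Mono;

struct Rat {
  long long n, d; // d > 0
};

static long long gcd_ll(long long a, long long b) {
  if (a < 0) a = -a;
  if (b < 0) b = -b;
  while (b) { long long t = a % b; a = b; b = t; }
  return a;
}

static const long long LIMIT = (1LL << 62);

static long long chk(__int128 v) {
  if (v >= (__int128)LIMIT || v <= -(__int128)LIMIT)
    stop("coefficient overflow in exact arithmetic");
  return (long long)v;
}

static Rat rat_norm(long long n, long long d) {
  if (d == 0) stop("zero denominator in rational");
  if (d < 0) { n = -n; d = -d; }
  if (n == 0) return {0, 1};
  long long g = gcd_ll(n, d);
  return {n / g, d / g};
}

static Rat rat_add(const Rat &a, const Rat &b) {
  __int128 n = (__int128)a.n * b.d + (__int128)b.n * a.d;
  __int128 d = (__int128)a.d * b.d;
  // reduce before overflow check where possible
  long long g1 = gcd_ll(a.d, b.d);
  if (g1 > 1) {
    n = (__int128)a.n * (b.d / g1) + (__int128)b.n * (a.d / g1);
    d = (__int128)(a.d / g1) * b.d;
  }
  return rat_norm(chk(n), chk(d));
}

static Rat rat_mul(const Rat &a, const Rat &b) {
  long long g1 = gcd_ll(a.n, b.d), g2 = gcd_ll(b.n, a.d);
  __int128 n = (__int128)(g1 ? a.n / g1 : a.n) * (g2 ? b.n / g2 : b.n);
  __int128 d = (__int128)(g2 ? a.d / g2 : a.d) * (g1 ? b.d / g1 : b.d);
  return rat_norm(chk(n), chk(d));
}

typedef std::map<Mono, Rat> Poly;

static Poly from_list(const List &p) {
  IntegerMatrix E = p["E"];
  NumericVector num = p["num"], den = p["den"];
  int t = E.nrow(), k = E.ncol();
  Poly out;
  for (int i = 0; i < t; ++i) {
    Mono m(k);
    for (int j = 0; j < k; ++j) m[j] = E(i, j);
    Rat c = rat_norm((long long)num[i], (long long)den[i]);
    if (c.n == 0) continue;
    auto it = out.find(m);
    if (it == out.end()) out[m] = c;
    else {
      it->second = rat_add(it->second, c);
      if (it->second.n == 0) out.erase(it);
    }
  }
  return out;
}

static const double DBL_EXACT = 9007199254740992.0; // 2^53

static List to_list(const Poly &p, int k) {
  int t = (int)p.size();
  IntegerMatrix E(t, k);
  NumericVector num(t), den(t);
  int i = 0;
  for (auto &kv : p) {
    for (int j = 0; j < k; ++j) E(i, j) = kv.first[j];
    if (kv.second.n >= (long long)DBL_EXACT || kv.second.n <= -(long long)DBL_EXACT ||
        kv.second.d >= (long long)DBL_EXACT)
      stop("coefficient overflow in exact arithmetic");
    num[i] = (double)kv.second.n;
    den[i] = (double)kv.second.d;
    ++i;
  }
  return List::create(_["E"] = E, _["num"] = num, _["den"] = den);
}

static int width(const List &p) { return as<IntegerMatrix>(p["E"]).ncol(); }

static void add_term(Poly &p, const Mono &m, const Rat &c) {
  if (c.n == 0) return;
  auto it = p.find(m);
  if (it == p.end()) p[m] = c;
  else {
    it->second = rat_add(it->second, c);
    if (it->second.n == 0) p.erase(it);
  }
}

static Poly poly_add(const Poly &a, const Poly &b) {
  Poly r = a;
  for (auto &kv : b) add_term(r, kv.first, kv.second);
  return r;
}

static Poly poly_neg(const Poly &a) {
  Poly r = a;
  for (auto &kv : r) kv.second.n = -kv.second.n;
  return r;
}

static Poly poly_mul(const Poly &a, const Poly &b) {
  Poly r;
  if (a.empty() || b.empty()) return r;
  int k = (int)a.begin()->first.size();
  Mono m(k);
  for (auto &ka : a)
    for (auto &kb : b) {
      for (int j = 0; j < k; ++j) m[j] = ka.first[j] + kb.first[j];
      add_term(r, m, rat_mul(ka.second, kb.second));
    }
  return r;
}

static Poly poly_pow(const Poly &a, int e, int k) {
  Poly r;
  r[Mono(k, 0)] = {1, 1};
  if (e == 0) return r;
  if (a.empty()) return Poly();
  for (int i = 0; i < e; ++i) r = poly_mul(r, a);
  return r;
}

static int poly_deg(const Poly &p, int v) {
  int d = 0;
  for (auto &kv : p) if (kv.first[v] > d) d = kv.first[v];
  return d;
}

static std::map<int, Poly> collect(const Poly &p, int v) {
  std::map<int, Poly> out;
  for (auto &kv : p) {
    Mono m = kv.first;
    int e = m[v];
    m[v] = 0;
    add_term(out[e], m, kv.second);
  }
  for (auto it = out.begin(); it != out.end();) {
    if (it->second.empty()) it = out.erase(it); else ++it;
  }
  return out;
}

// substitute variable v := N/D, homogenised by D^deg (valid for equations
// and used with explicit denominator tracking for values)
static bool mono_less(const Mono &a, const Mono &b);

static Poly subs_rat(const Poly &p, int v, const Poly &N, const Poly &D, int k) {
  int dmax = poly_deg(p, v);
  if (dmax == 0) return p;
  std::map<int, Poly> col = collect(p, v);
  Poly r;
  for (auto &kv : col) {
    Poly term = poly_mul(poly_mul(kv.second, poly_pow(N, kv.first, k)),
                         poly_pow(D, dmax - kv.first, k));
    r = poly_add(r, term);
  }
  return r;
}

static Poly content_norm(const Poly &p) {
  if (p.empty()) return p;
  long long g = 0, l = 1;
  for (auto &kv : p) {
    g = gcd_ll(g, kv.second.n);
    long long gg = gcd_ll(l, kv.second.d);
    l = chk((__int128)(l / gg) * kv.second.d);
  }
  Mono lead = p.begin()->first;
  for (auto &kv : p) if (mono_less(lead, kv.first)) lead = kv.first;
  Rat f = rat_norm(l, g);
  Rat lc = p.at(lead);
  if (rat_mul(lc, f).n < 0) f.n = -f.n;
  Poly r;
  for (auto &kv : p) add_term(r, kv.first, rat_mul(kv.second, f));
  return r;
}

// joint content normalisation of a value pair (preserves num/den ratio)
static void pair_norm(Poly &num, Poly &den) {
  long long g = 0, l = 1;
  for (auto *pp : {&num, &den})
    for (auto &kv : *pp) {
      g = gcd_ll(g, kv.second.n);
      long long gg = gcd_ll(l, kv.second.d);
      l = chk((__int128)(l / gg) * kv.second.d);
    }
  if (g == 0) return;
  Rat f = rat_norm(l, g);
  Poly rn, rd;
  for (auto &kv : num) add_term(rn, kv.first, rat_mul(kv.second, f));
  for (auto &kv : den) add_term(rd, kv.first, rat_mul(kv.second, f));
  num = rn; den = rd;
}

// [[Rcpp::export(name = ".pk_add")]]
List pk_add(List a, List b) { return to_list(poly_add(from_list(a), from_list(b)), width(a)); }

// [[Rcpp::export(name = ".pk_neg")]]
List pk_neg(List a) { return to_list(poly_neg(from_list(a)), width(a)); }

// [[Rcpp::export(name = ".pk_mul")]]
List pk_mul(List a, List b) { return to_list(poly_mul(from_list(a), from_list(b)), width(a)); }

// [[Rcpp::export(name = ".pk_pow")]]
List pk_pow(List a, int e) { int k = width(a); return to_list(poly_pow(from_list(a), e, k), width(a)); }

// [[Rcpp::export(name = ".pk_scale")]]
List pk_scale(List a, double n, double d) {
  Poly p = from_list(a);
  Rat c = rat_norm((long long)n, (long long)d);
  Poly r;
  for (auto &kv : p) add_term(r, kv.first, rat_mul(kv.second, c));
  return to_list(r, width(a));
}

// [[Rcpp::export(name = ".pk_deg")]]
int pk_deg(List a, int v) { return poly_deg(from_list(a), v - 1); }

// [[Rcpp::export(name = ".pk_collect")]]
List pk_collect(List a, int v) {
  std::map<int, Poly> col = collect(from_list(a), v - 1);
  int k = width(a);
  List out;
  IntegerVector degs;
  for (auto &kv : col) {
    degs.push_back(kv.first);
    out.push_back(to_list(kv.second, k));
  }
  return List::create(_["deg"] = degs, _["coef"] = out);
}

// [[Rcpp::export(name = ".pk_subs_rat")]]
List pk_subs_rat(List a, int v, List N, List D, bool normalize = false) {
  Poly r = subs_rat(from_list(a), v - 1, from_list(N), from_list(D), width(a));
  if (normalize) r = content_norm(r);
  return to_list(r, width(a));
}

// exact division: returns p / f, or NULL when not exact.
// deglex order over the full fixed variable vector (admissible).
static bool mono_less(const Mono &a, const Mono &b) {
  int ta = 0, tb = 0;
  for (size_t i = 0; i < a.size(); ++i) { ta += a[i]; tb += b[i]; }
  if (ta != tb) return ta < tb;
  return a < b;
}

// [[Rcpp::export(name = ".pk_divexact")]]
SEXP pk_divexact(List a, List f) {
  Poly p = from_list(a), g = from_list(f);
  int k = width(a);
  if (g.empty()) return R_NilValue;
  if (p.empty()) return to_list(Poly(), k);
  // leading term of g
  Mono gl = g.begin()->first;
  for (auto &kv : g) if (mono_less(gl, kv.first)) gl = kv.first;
  Rat gc = g.at(gl);
  Poly q;
  int guard = 0;
  while (!p.empty()) {
    if (++guard > 20000) return R_NilValue;
    Mono pl = p.begin()->first;
    for (auto &kv : p) if (mono_less(pl, kv.first)) pl = kv.first;
    Mono m(k);
    for (int j = 0; j < k; ++j) {
      int e = pl[j] - gl[j];
      if (e < 0) return R_NilValue;
      m[j] = e;
    }
    Rat c = rat_mul(p.at(pl), rat_norm(gc.d, gc.n));
    add_term(q, m, c);
    Poly sub;
    sub[m] = c;
    p = poly_add(p, poly_neg(poly_mul(sub, g)));
  }
  return to_list(q, k);
}

// pseudo-remainder of f by g with respect to variable v (1-based);
// NULL if the intermediate grows past maxTerms.
// [[Rcpp::export(name = ".pk_prem")]]
SEXP pk_prem(List fa, List ga, int v, int maxTerms) {
  Poly f = from_list(fa), g = from_list(ga);
  int k = width(fa);
  int vi = v - 1;
  int dg = poly_deg(g, vi);
  if (dg == 0) return R_NilValue;
  std::map<int, Poly> colg = collect(g, vi);
  Poly lcg = colg[dg];
  Poly r = f;
  while (!r.empty() && poly_deg(r, vi) >= dg) {
    int dr = poly_deg(r, vi);
    std::map<int, Poly> colr = collect(r, vi);
    Poly lcr = colr[dr];
    Poly shift = g;
    if (dr > dg) {
      Poly xm;
      Mono m(k, 0);
      m[vi] = dr - dg;
      xm[m] = {1, 1};
      shift = poly_mul(xm, g);
    }
    r = poly_add(poly_mul(lcg, r), poly_neg(poly_mul(lcr, shift)));
    r = content_norm(r);
    if ((int)r.size() > maxTerms) return R_NilValue;
  }
  return to_list(r, k);
}

// divide out numeric content and normalise sign of the (deglex) leading term
// [[Rcpp::export(name = ".pk_content_norm")]]
List pk_content_norm(List a) {
  Poly p = from_list(a);
  int k = width(a);
  if (p.empty()) return to_list(p, k);
  long long g = 0, l = 1;
  for (auto &kv : p) {
    g = gcd_ll(g, kv.second.n);
    long long gg = gcd_ll(l, kv.second.d);
    l = chk((__int128)(l / gg) * kv.second.d);
  }
  Mono lead = p.begin()->first;
  for (auto &kv : p) if (mono_less(lead, kv.first)) lead = kv.first;
  Rat f = rat_norm(l, g);
  if (rat_mul(p.at(lead), f).n < 0) f.n = -f.n;
  Poly r;
  for (auto &kv : p) add_term(r, kv.first, rat_mul(kv.second, f));
  return to_list(r, k);
}

// common monomial (per-variable minimum exponents)
// [[Rcpp::export(name = ".pk_mono_mins")]]
IntegerVector pk_mono_mins(List a) {
  Poly p = from_list(a);
  int k = width(a);
  IntegerVector mins(k);
  if (p.empty()) return mins;
  bool first = true;
  for (auto &kv : p) {
    for (int j = 0; j < k; ++j)
      mins[j] = first ? kv.first[j] : std::min((int)mins[j], kv.first[j]);
    first = false;
  }
  return mins;
}

// [[Rcpp::export(name = ".pk_mono_divide")]]
List pk_mono_divide(List a, IntegerVector mins) {
  Poly p = from_list(a);
  int k = width(a);
  Poly r;
  for (auto &kv : p) {
    Mono m = kv.first;
    for (int j = 0; j < k; ++j) m[j] -= mins[j];
    r[m] = kv.second;
  }
  return to_list(r, k);
}

// reduce even powers of radical variables: g^2 -> num/den, homogenising the
// whole polynomial (equations only, or paired with the returned multiplier).
// radicals: list of list(v = 1-based index, num = poly, den = poly), in order.
// Returns list(p = reduced poly, mul = poly the original was multiplied by).
// [[Rcpp::export(name = ".pk_gred")]]
List pk_gred(List a, List radicals, bool normalize = false) {
  Poly p = from_list(a);
  int k = width(a);
  Poly mul;
  mul[Mono(k, 0)] = {1, 1};
  bool again = true;
  int guard = 0;
  while (again) {
    if (++guard > 10) stop("radical reduction did not stabilise");
    again = false;
    for (int i = 0; i < radicals.size(); ++i) {
      List rad = radicals[i];
      int v = as<int>(rad["v"]) - 1;
      if (poly_deg(p, v) < 2) continue;
      Poly N = from_list(as<List>(rad["num"]));
      Poly D = from_list(as<List>(rad["den"]));
      std::map<int, Poly> col = collect(p, v);
      int M = 0;
      for (auto &kv : col) M = std::max(M, kv.first / 2);
      Poly r;
      for (auto &kv : col) {
        int q = kv.first / 2, rr = kv.first % 2;
        Poly term = poly_mul(poly_mul(kv.second, poly_pow(N, q, k)), poly_pow(D, M - q, k));
        if (rr) {
          Poly gv;
          Mono m(k, 0);
          m[v] = 1;
          gv[m] = {1, 1};
          term = poly_mul(term, gv);
        }
        r = poly_add(r, term);
      }
      p = r;
      mul = poly_mul(mul, poly_pow(D, M, k));
      again = true;
    }
    // only loop again if some radical still has degree >= 2
    bool high = false;
    for (int i = 0; i < radicals.size(); ++i) {
      int v = as<int>(as<List>(radicals[i])["v"]) - 1;
      if (poly_deg(p, v) >= 2) { high = true; break; }
    }
    again = high;
  }
  if (normalize) p = content_norm(p);
  return List::create(_["p"] = to_list(p, k), _["mul"] = to_list(mul, k));
}

struct RadDef { int v; Poly N, D; };

static std::vector<RadDef> rad_defs(const List &radicals) {
  std::vector<RadDef> out;
  for (int i = 0; i < radicals.size(); ++i) {
    List r = radicals[i];
    out.push_back({as<int>(r["v"]) - 1,
                   from_list(as<List>(r["num"])),
                   from_list(as<List>(r["den"]))});
  }
  return out;
}

// reduce even radical powers in p; multiplies p by den^M per radical and
// reports the accumulated multiplier
static Poly gred_poly(Poly p, const std::vector<RadDef> &rads, Poly &mul, int k) {
  bool again = true;
  int guard = 0;
  while (again) {
    if (++guard > 12) stop("radical reduction did not stabilise");
    again = false;
    for (auto &rd : rads) {
      if (poly_deg(p, rd.v) < 2) continue;
      std::map<int, Poly> col = collect(p, rd.v);
      int M = 0;
      for (auto &kv : col) M = std::max(M, kv.first / 2);
      Poly r;
      for (auto &kv : col) {
        int q = kv.first / 2, rr = kv.first % 2;
        Poly term = poly_mul(poly_mul(kv.second, poly_pow(rd.N, q, k)), poly_pow(rd.D, M - q, k));
        if (rr) {
          Poly gv; Mono m(k, 0); m[rd.v] = 1; gv[m] = {1, 1};
          term = poly_mul(term, gv);
        }
        r = poly_add(r, term);
      }
      p = r;
      mul = poly_mul(mul, poly_pow(rd.D, M, k));
    }
    for (auto &rd : rads) if (poly_deg(p, rd.v) >= 2) { again = true; break; }
  }
  return p;
}

// value pair: reduce radicals, rationalise the denominator, keep the pair
// jointly normalised throughout
// [[Rcpp::export(name = ".pk_pair_rationalize")]]
List pk_pair_rationalize(List numL, List denL, List radicals) {
  int k = width(numL);
  Poly num = from_list(numL), den = from_list(denL);
  std::vector<RadDef> rads = rad_defs(radicals);
  Poly m1, m2;
  m1[Mono(k, 0)] = {1, 1}; m2[Mono(k, 0)] = {1, 1};
  num = gred_poly(num, rads, m1, k);
  den = gred_poly(den, rads, m2, k);
  num = poly_mul(num, m2); den = poly_mul(den, m1);
  pair_norm(num, den);
  for (int i = (int)rads.size() - 1; i >= 0; --i) {
    if (poly_deg(den, rads[i].v) > 0) {
      std::map<int, Poly> col = collect(den, rads[i].v);
      Poly ev = col.count(0) ? col[0] : Poly();
      Poly od = col.count(1) ? col[1] : Poly();
      Poly gv; Mono m(k, 0); m[rads[i].v] = 1; gv[m] = {1, 1};
      Poly conj = poly_add(ev, poly_neg(poly_mul(od, gv)));
      num = poly_mul(num, conj); den = poly_mul(den, conj);
      Poly mm1, mm2;
      mm1[Mono(k, 0)] = {1, 1}; mm2[Mono(k, 0)] = {1, 1};
      num = gred_poly(num, rads, mm1, k);
      den = gred_poly(den, rads, mm2, k);
      num = poly_mul(num, mm2); den = poly_mul(den, mm1);
      pair_norm(num, den);
    }
  }
  return List::create(_["num"] = to_list(num, k), _["den"] = to_list(den, k));
}

// homogenised substitution of w := wn/wd into the value pair (vn, vd)
// [[Rcpp::export(name = ".pk_pair_subs")]]
List pk_pair_subs(List vnL, List vdL, int w, List wnL, List wdL) {
  int k = width(vnL);
  Poly vn = from_list(vnL), vd = from_list(vdL);
  Poly wn = from_list(wnL), wd = from_list(wdL);
  int wi = w - 1;
  int dn = poly_deg(vn, wi), dd = poly_deg(vd, wi);
  int D = std::max(dn, dd);
  Poly n2 = poly_mul(subs_rat(vn, wi, wn, wd, k), poly_pow(wd, D - dn, k));
  Poly d2 = poly_mul(subs_rat(vd, wi, wn, wd, k), poly_pow(wd, D - dd, k));
  pair_norm(n2, d2);
  return List::create(_["num"] = to_list(n2, k), _["den"] = to_list(d2, k));
}

// numeric (possibly complex) evaluation; vals has one entry per variable
// [[Rcpp::export(name = ".pk_eval")]]
ComplexVector pk_eval(List a, ComplexVector vals) {
  IntegerMatrix E = a["E"];
  NumericVector num = a["num"], den = a["den"];
  int t = E.nrow(), k = E.ncol();
  std::complex<double> acc(0, 0);
  for (int i = 0; i < t; ++i) {
    std::complex<double> v(num[i] / den[i], 0);
    for (int j = 0; j < k; ++j) {
      int e = E(i, j);
      if (e == 0) continue;
      std::complex<double> base(vals[j].r, vals[j].i);
      for (int q = 0; q < e; ++q) v *= base;
    }
    acc += v;
  }
  ComplexVector out(1);
  out[0].r = acc.real();
  out[0].i = acc.imag();
  return out;
}

// ---------------------------------------------------------------------------
// Branch verification over Z_p.  Back-substituting a solved branch into the
// original system can involve integers beyond 64-bit range, so the identity
// "every equation reduces to the zero polynomial" is checked in Z_p for a
// battery of large primes instead; a nonzero integer coefficient would have
// to be divisible by the product of all primes (~1e75) to escape detection.
// ---------------------------------------------------------------------------

typedef std::map<Mono, long long> PolyP;

static long long mod_inv(long long a, long long p) {
  long long t = 0, newt = 1, r = p, newr = a % p;
  if (newr < 0) newr += p;
  while (newr != 0) {
    long long q = r / newr;
    long long tmp = t - q * newt; t = newt; newt = tmp;
    tmp = r - q * newr; r = newr; newr = tmp;
  }
  if (r > 1) stop("denominator not invertible mod p");
  return t < 0 ? t + p : t;
}

static PolyP fromQ(const List &a, long long p) {
  Poly q = from_list(a);
  PolyP out;
  for (auto &kv : q) {
    long long n = kv.second.n % p;
    if (n < 0) n += p;
    long long c = (long long)(((__int128)n * mod_inv(kv.second.d % p, p)) % p);
    if (c) out[kv.first] = c;
  }
  return out;
}

static void addp(PolyP &r, const Mono &m, long long c, long long p) {
  if (!c) return;
  auto it = r.find(m);
  if (it == r.end()) r[m] = c;
  else {
    long long v = (it->second + c) % p;
    if (v) it->second = v; else r.erase(it);
  }
}

static PolyP mulp(const PolyP &a, const PolyP &b, long long p) {
  PolyP r;
  if (a.empty() || b.empty()) return r;
  int k = (int)a.begin()->first.size();
  Mono m(k);
  for (auto &ka : a)
    for (auto &kb : b) {
      for (int j = 0; j < k; ++j) m[j] = ka.first[j] + kb.first[j];
      addp(r, m, (long long)(((__int128)ka.second * kb.second) % p), p);
    }
  return r;
}

static PolyP powp(const PolyP &a, int e, int k, long long p) {
  PolyP r;
  r[Mono(k, 0)] = 1;
  for (int i = 0; i < e; ++i) r = mulp(r, a, p);
  return r;
}

static int degp(const PolyP &a, int v) {
  int d = 0;
  for (auto &kv : a) if (kv.first[v] > d) d = kv.first[v];
  return d;
}

static PolyP subsp(const PolyP &a, int v, const PolyP &N, const PolyP &D,
                   int k, long long p) {
  int dmax = degp(a, v);
  if (dmax == 0) return a;
  std::map<int, PolyP> col;
  for (auto &kv : a) {
    Mono m = kv.first;
    int e = m[v]; m[v] = 0;
    addp(col[e], m, kv.second, p);
  }
  PolyP r;
  for (auto &kv : col) {
    PolyP term = mulp(mulp(kv.second, powp(N, kv.first, k, p), p),
                      powp(D, dmax - kv.first, k, p), p);
    for (auto &t : term) addp(r, t.first, t.second, p);
  }
  return r;
}

// [[Rcpp::export(name = ".pk_verify_modp")]]
bool pk_verify_modp(List eqs, List sols, List radicals) {
  static const long long primes[] = {2147483629LL, 2147483587LL,
                                     2147483563LL, 2147483549LL};
  for (long long p : primes) {
    for (int ei = 0; ei < eqs.size(); ++ei) {
      List eq = eqs[ei];
      int k = width(eq);
      PolyP e = fromQ(eq, p);
      for (int si = 0; si < sols.size(); ++si) {
        List s = sols[si];
        int v = as<int>(s["v"]) - 1;
        PolyP N = fromQ(as<List>(s["num"]), p);
        PolyP D = fromQ(as<List>(s["den"]), p);
        e = subsp(e, v, N, D, k, p);
      }
      // reduce radical powers g^2 -> num/den
      bool again = true;
      int guard = 0;
      while (again) {
        if (++guard > 12) stop("radical reduction did not stabilise");
        again = false;
        for (int ri = 0; ri < radicals.size(); ++ri) {
          List rad = radicals[ri];
          int v = as<int>(rad["v"]) - 1;
          if (degp(e, v) < 2) continue;
          PolyP N = fromQ(as<List>(rad["num"]), p);
          PolyP D = fromQ(as<List>(rad["den"]), p);
          std::map<int, PolyP> col;
          for (auto &kv : e) {
            Mono m = kv.first;
            int ex = m[v]; m[v] = 0;
            addp(col[ex], m, kv.second, p);
          }
          int M = 0;
          for (auto &kv : col) M = std::max(M, kv.first / 2);
          PolyP r;
          for (auto &kv : col) {
            int q = kv.first / 2, rr = kv.first % 2;
            PolyP term = mulp(mulp(kv.second, powp(N, q, k, p), p),
                              powp(D, M - q, k, p), p);
            if (rr) {
              PolyP gv; Mono m(k, 0); m[v] = 1; gv[m] = 1;
              term = mulp(term, gv, p);
            }
            for (auto &t : term) addp(r, t.first, t.second, p);
          }
          e = r;
          again = true;
        }
        bool high = false;
        for (int ri = 0; ri < radicals.size(); ++ri) {
          int v = as<int>(as<List>(radicals[ri])["v"]) - 1;
          if (degp(e, v) >= 2) { high = true; break; }
        }
        again = high;
      }
      if (!e.empty()) return false;
    }
  }
  return true;
}
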