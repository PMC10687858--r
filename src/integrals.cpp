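// McMurchie-Davidson integrals over contracted Gaussian shells.
//
// All integrals are evaluated in Cartesian primitives and transformed to
// real solid-harmonic ("pure") components where requested.  Contracted
// functions are normalised to unit self-overlap at shell set-up, so every
// downstream tensor refers to normalised AOs.  Angular momenta up to l = 3
// (f) are supported; that covers the even-tempered nuclear fitting ladders
// (10s10p10d10f) and the synthetic JK fitting sets shipped with the package.
//
// Auxiliary ("fitting") functions enter the same two-particle kernel as a
// shell paired with a dummy zero-exponent s function, which reduces the
// Hermite expansion of the pair to that of the single Gaussian.  This gives
// one code path for (mu nu|lam sig), (mu nu|A) and (A|B).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int LMAX = 4;

// ---------------------------------------------------------------- utilities

static double dfact(int n) { // (n)!! with (-1)!! = 1
  double r = 1.0;
  for (int k = n; k > 1; k -= 2) r *= k;
  return r;
}

// \int x^n exp(-g x^2) dx over R, n even (0 otherwise)
static double gauss1d(int n, double g) {
  if (n % 2 == 1) return 0.0;
  return dfact(n - 1) / std::pow(2.0 * g, n / 2) * std::sqrt(M_PI / g);
}

struct CartComp { int x, y, z; };

static std::vector<CartComp> cart_list(int l) {
  std::vector<CartComp> v;
  for (int i = l; i >= 0; --i)
    for (int j = l - i; j >= 0; --j)
      v.push_back({i, j, l - i - j});
  return v;
}

static int ncart(int l) { return (l + 1) * (l + 2) / 2; }

// raw (unnormalised) same-centre overlap of two Cartesian monomial
// Gaussians with combined exponent g
static double raw_overlap(const CartComp& a, const CartComp& b, double g) {
  return gauss1d(a.x + b.x, g) * gauss1d(a.y + b.y, g) * gauss1d(a.z + b.z, g);
}

// --------------------------------------------------------- solid harmonics

// rows of the (unnormalised) real solid harmonic polynomials in the
// lexicographic Cartesian basis; row scale is fixed later by normalisation
static arma::mat solid_T(int l) {
  arma::mat T;
  if (l == 0) { T.eye(1, 1); return T; }
  if (l == 1) { T.eye(3, 3); return T; }
  if (l == 2) {
    // cart order xx xy xz yy yz zz ; rows m = -2..2
    T.zeros(5, 6);
    T(0, 1) = 1.0;                                 // xy
    T(1, 4) = 1.0;                                 // yz
    T(2, 0) = -0.5; T(2, 3) = -0.5; T(2, 5) = 1.0; // z^2 - (x^2+y^2)/2
    T(3, 2) = 1.0;                                 // xz
    T(4, 0) = 1.0; T(4, 3) = -1.0;                 // x^2 - y^2
    return T;
  }
  if (l == 3) {
    // cart order xxx xxy xxz xyy xyz xzz yyy yyz yzz zzz ; rows m = -3..3
    T.zeros(7, 10);
    T(0, 1) = 3.0;  T(0, 6) = -1.0;                 // 3x^2y - y^3
    T(1, 4) = 1.0;                                  // xyz
    T(2, 8) = 4.0;  T(2, 1) = -1.0; T(2, 6) = -1.0; // y(4z^2-x^2-y^2)
    T(3, 9) = 2.0;  T(3, 2) = -3.0; T(3, 7) = -3.0; // z(2z^2-3x^2-3y^2)
    T(4, 5) = 4.0;  T(4, 0) = -1.0; T(4, 3) = -1.0; // x(4z^2-x^2-y^2)
    T(5, 2) = 1.0;  T(5, 7) = -1.0;                 // z(x^2-y^2)
    T(6, 0) = 1.0;  T(6, 3) = -3.0;                 // x^3 - 3xy^2
    return T;
  }
  if (l == 4) {
    // cart order xxxx xxxy xxxz xxyy xxyz xxzz xyyy xyyz xyzz xzzz
    //            yyyy yyyz yyzz yzzz zzzz ; rows m = -4..4
    T.zeros(9, 15);
    T(0, 1) = 1.0;  T(0, 6) = -1.0;                  // xy(x^2-y^2)
    T(1, 4) = 3.0;  T(1, 11) = -1.0;                 // yz(3x^2-y^2)
    T(2, 8) = 6.0;  T(2, 1) = -1.0;  T(2, 6) = -1.0; // xy(6z^2-x^2-y^2)
    T(3, 13) = 4.0; T(3, 4) = -3.0;  T(3, 11) = -3.0;// yz(4z^2-3x^2-3y^2)
    T(4, 0) = 3.0;  T(4, 10) = 3.0;  T(4, 14) = 8.0; // 35z^4-30z^2r^2+3r^4
    T(4, 3) = 6.0;  T(4, 5) = -24.0; T(4, 12) = -24.0;
    T(5, 9) = 4.0;  T(5, 2) = -3.0;  T(5, 7) = -3.0; // xz(4z^2-3x^2-3y^2)
    T(6, 5) = 6.0;  T(6, 12) = -6.0;                 // (x^2-y^2)(6z^2-x^2-y^2)
    T(6, 0) = -1.0; T(6, 10) = 1.0;
    T(7, 2) = 1.0;  T(7, 7) = -3.0;                  // xz(x^2-3y^2)
    T(8, 0) = 1.0;  T(8, 3) = -6.0;  T(8, 10) = 1.0; // x^4-6x^2y^2+y^4
    return T;
  }
  stop("angular momentum l > 4 is not supported");
  return T;
}

// -------------------------------------------------------------------- Shell

struct Shell {
  int l;
  bool pure;
  arma::vec3 R;
  arma::vec ex, cf;   // cf carry primitive norms after set-up
  arma::mat W;        // (nfun x ncart) component transform incl. norms
  int nc() const { return ncart(l); }
  int nf() const { return pure ? 2 * l + 1 : nc(); }
};

static std::vector<Shell> parse_shells(const List& shells) {
  std::vector<Shell> out;
  out.reserve(shells.size());
  for (int s = 0; s < shells.size(); ++s) {
    List sh = shells[s];
    Shell S;
    S.l = as<int>(sh["l"]);
    if (S.l < 0 || S.l > LMAX) stop("shell angular momentum must be in 0..4");
    S.pure = as<bool>(sh["pure"]);
    NumericVector c0 = sh["center"];
    S.R = {c0[0], c0[1], c0[2]};
    S.ex = as<arma::vec>(sh["exps"]);
    S.cf = as<arma::vec>(sh["coefs"]);
    if (S.ex.n_elem != S.cf.n_elem || S.ex.n_elem == 0)
      stop("shell primitive arrays are inconsistent");
    if (S.ex.min() <= 0.0) stop("shell exponents must be strictly positive");
    // primitive normalisation against the (l,0,0) monomial
    std::vector<CartComp> cc = cart_list(S.l);
    for (arma::uword k = 0; k < S.ex.n_elem; ++k) {
      double o = raw_overlap(cc[0], cc[0], 2.0 * S.ex(k));
      S.cf(k) /= std::sqrt(o);
    }
    // component transform with contracted normalisation
    arma::mat T = S.pure ? solid_T(S.l) : arma::eye(S.nc(), S.nc());
    arma::vec nrm(T.n_rows, arma::fill::zeros);
    for (arma::uword m = 0; m < T.n_rows; ++m) {
      double acc = 0.0;
      for (arma::uword k = 0; k < S.ex.n_elem; ++k)
        for (arma::uword k2 = 0; k2 < S.ex.n_elem; ++k2) {
          double g = S.ex(k) + S.ex(k2), ck = S.cf(k) * S.cf(k2);
          for (int p = 0; p < S.nc(); ++p) {
            if (T(m, p) == 0.0) continue;
            for (int q = 0; q < S.nc(); ++q) {
              if (T(m, q) == 0.0) continue;
              acc += ck * T(m, p) * T(m, q) * raw_overlap(cc[p], cc[q], g);
            }
          }
        }
      nrm(m) = std::sqrt(acc);
    }
    S.W = T;
    for (arma::uword m = 0; m < T.n_rows; ++m) S.W.row(m) /= nrm(m);
    out.push_back(S);
  }
  return out;
}

static int basis_nf(const std::vector<Shell>& sh) {
  int n = 0;
  for (const Shell& s : sh) n += s.nf();
  return n;
}

// ----------------------------------------------------- Hermite E recursion

// E[(i*(jmax+1)+j)*tdim + t], t = 0..i+j
static void ecoef(int imax, int jmax, double a, double b, double AB,
                  std::vector<double>& E) {
  int tdim = imax + jmax + 1;
  E.assign((size_t)(imax + 1) * (jmax + 1) * tdim, 0.0);
  double p = a + b;
  double mu = (b > 0.0) ? a * b / p : 0.0;
  double XPA = -b * AB / p, XPB = a * AB / p;
  auto id = [&](int i, int j, int t) { return (size_t)(i * (jmax + 1) + j) * tdim + t; };
  E[id(0, 0, 0)] = std::exp(-mu * AB * AB);
  for (int i = 0; i < imax; ++i)
    for (int t = 0; t <= i + 1; ++t) {
      double v = 0.0;
      if (t > 0) v += E[id(i, 0, t - 1)] / (2.0 * p);
      if (t <= i) v += XPA * E[id(i, 0, t)];
      if (t + 1 <= i) v += (t + 1) * E[id(i, 0, t + 1)];
      E[id(i + 1, 0, t)] = v;
    }
  for (int j = 0; j < jmax; ++j)
    for (int i = 0; i <= imax; ++i)
      for (int t = 0; t <= i + j + 1; ++t) {
        double v = 0.0;
        if (t > 0) v += E[id(i, j, t - 1)] / (2.0 * p);
        if (t <= i + j) v += XPB * E[id(i, j, t)];
        if (t + 1 <= i + j) v += (t + 1) * E[id(i, j, t + 1)];
        E[id(i, j + 1, t)] = v;
      }
}

// ------------------------------------------------------------ Boys, R_tuv

static void boys(int mmax, double T, double* F) {
  if (T > 33.0) {
    F[0] = 0.5 * std::sqrt(M_PI / T);
    double eT = std::exp(-T);
    for (int m = 0; m < mmax; ++m) F[m + 1] = ((2 * m + 1) * F[m] - eT) / (2.0 * T);
  } else {
    double term = 1.0 / (2 * mmax + 1), sum = term;
    for (int k = 1; k < 500; ++k) {
      term *= 2.0 * T / (2 * mmax + 2 * k + 1);
      sum += term;
      if (term < 1e-17 * sum) break;
    }
    double eT = std::exp(-T);
    F[mmax] = eT * sum;
    for (int m = mmax; m > 0; --m) F[m - 1] = (2.0 * T * F[m] + eT) / (2 * m - 1);
  }
}

// Hermite Coulomb integrals R^0_{tuv} for t+u+v <= tmax, cube-indexed
static void rtensor(int tmax, double p, double X, double Y, double Z,
                    std::vector<double>& R0) {
  int dim = tmax + 1;
  size_t d3 = (size_t)dim * dim * dim;
  double T = p * (X * X + Y * Y + Z * Z);
  std::vector<double> F(tmax + 1);
  boys(tmax, T, F.data());
  std::vector<double> buf((size_t)(tmax + 1) * d3, 0.0);
  auto id = [&](int t, int u, int v) { return ((size_t)t * dim + u) * dim + v; };
  for (int m = tmax; m >= 0; --m) {
    double* Rm = &buf[(size_t)m * d3];
    const double* Rm1 = (m < tmax) ? &buf[(size_t)(m + 1) * d3] : nullptr;
    Rm[id(0, 0, 0)] = std::pow(-2.0 * p, m) * F[m];
    int smax = tmax - m;
    for (int s = 1; s <= smax; ++s)
      for (int t = 0; t <= s; ++t)
        for (int u = 0; u <= s - t; ++u) {
          int v = s - t - u;
          double val = 0.0;
          if (t > 0) {
            if (t > 1) val += (t - 1) * Rm1[id(t - 2, u, v)];
            val += X * Rm1[id(t - 1, u, v)];
          } else if (u > 0) {
            if (u > 1) val += (u - 1) * Rm1[id(t, u - 2, v)];
            val += Y * Rm1[id(t, u - 1, v)];
          } else {
            if (v > 1) val += (v - 1) * Rm1[id(t, u, v - 2)];
            val += Z * Rm1[id(t, u, v - 1)];
          }
          Rm[id(t, u, v)] = val;
        }
  }
  R0.assign(buf.begin(), buf.begin() + d3);
}

// -------------------------------------------------------------- shell pairs

struct PrimPair {
  double p, c;          // combined exponent, coefficient product
  arma::vec3 P;
  std::vector<double> Ex, Ey, Ez;
};

struct ShellPair {
  int i, j;             // shell indices (j = -1 for a bare fitting function)
  int la, lb;
  int nfa, nfb, nca, ncb;
  std::vector<PrimPair> pp;
  arma::mat WW;         // kron(Wa, Wb), (nfa*nfb x nca*ncb)
  double q;             // Schwarz bound sqrt(max (ab|ab))
};

static ShellPair make_pair(const std::vector<Shell>& sh, int i, int j) {
  ShellPair P;
  P.i = i; P.j = j;
  const Shell& A = sh[i];
  P.la = A.l; P.nfa = A.nf(); P.nca = A.nc();
  if (j >= 0) {
    const Shell& B = sh[j];
    P.lb = B.l; P.nfb = B.nf(); P.ncb = B.nc();
    P.WW = arma::kron(A.W, B.W);
    for (arma::uword ka = 0; ka < A.ex.n_elem; ++ka)
      for (arma::uword kb = 0; kb < B.ex.n_elem; ++kb) {
        PrimPair q;
        double a = A.ex(ka), b = B.ex(kb);
        q.p = a + b;
        q.c = A.cf(ka) * B.cf(kb);
        q.P = (a * A.R + b * B.R) / q.p;
        ecoef(P.la, P.lb, a, b, A.R(0) - B.R(0), q.Ex);
        ecoef(P.la, P.lb, a, b, A.R(1) - B.R(1), q.Ey);
        ecoef(P.la, P.lb, a, b, A.R(2) - B.R(2), q.Ez);
        // screen vanishing primitive pairs
        if (std::fabs(q.Ex[0] * q.Ey[0] * q.Ez[0] * q.c) > 1e-18 ||
            (P.la + P.lb) > 0)
          P.pp.push_back(q);
      }
  } else { // single fitting function paired with dummy zero-exponent s
    P.lb = 0; P.nfb = 1; P.ncb = 1;
    P.WW = A.W;
    for (arma::uword ka = 0; ka < A.ex.n_elem; ++ka) {
      PrimPair q;
      q.p = A.ex(ka);
      q.c = A.cf(ka);
      q.P = A.R;
      ecoef(P.la, 0, A.ex(ka), 0.0, 0.0, q.Ex);
      ecoef(P.la, 0, A.ex(ka), 0.0, 0.0, q.Ey);
      ecoef(P.la, 0, A.ex(ka), 0.0, 0.0, q.Ez);
      P.pp.push_back(q);
    }
  }
  P.q = 0.0;
  return P;
}

// Cartesian ERI block (bra pair | ket pair), chemists' notation
static arma::mat eri_block_cart(const ShellPair& B, const ShellPair& K) {
  int la = B.la, lb = B.lb, lc = K.la, ld = K.lb;
  std::vector<CartComp> ca = cart_list(la), cb = cart_list(lb),
                        cc = cart_list(lc), cd = cart_list(ld);
  int nab = B.nca * B.ncb, ncd = K.nca * K.ncb;
  int dimb = la + lb + 1, dimk = lc + ld + 1;
  int tmax = la + lb + lc + ld;
  int rdim = tmax + 1;
  arma::mat out(nab, ncd, arma::fill::zeros);
  std::vector<double> R0;
  arma::mat Theta((size_t)dimb * dimb * dimb, ncd);
  int tdb = la + lb + 1, tdk = lc + ld + 1; // t stride inside E arrays
  for (const PrimPair& pb : B.pp)
    for (const PrimPair& pk : K.pp) {
      double alpha = pb.p * pk.p / (pb.p + pk.p);
      arma::vec3 PQ = pb.P - pk.P;
      rtensor(tmax, alpha, PQ(0), PQ(1), PQ(2), R0);
      double pref = 2.0 * std::pow(M_PI, 2.5) /
                    (pb.p * pk.p * std::sqrt(pb.p + pk.p)) * pb.c * pk.c;
      auto rid = [&](int t, int u, int v) { return ((size_t)t * rdim + u) * rdim + v; };
      Theta.zeros();
      // ket Hermite contraction
      for (int c = 0; c < K.nca; ++c)
        for (int d = 0; d < K.ncb; ++d) {
          int cdi = c * K.ncb + d;
          int ux = cc[c].x + cd[d].x, uy = cc[c].y + cd[d].y, uz = cc[c].z + cd[d].z;
          const double* Ex = &pk.Ex[(size_t)(cc[c].x * (ld + 1) + cd[d].x) * tdk];
          const double* Ey = &pk.Ey[(size_t)(cc[c].y * (ld + 1) + cd[d].y) * tdk];
          const double* Ez = &pk.Ez[(size_t)(cc[c].z * (ld + 1) + cd[d].z) * tdk];
          for (int u = 0; u <= ux; ++u) {
            if (Ex[u] == 0.0) continue;
            for (int v = 0; v <= uy; ++v) {
              if (Ey[v] == 0.0) continue;
              double exy = Ex[u] * Ey[v];
              for (int w = 0; w <= uz; ++w) {
                if (Ez[w] == 0.0) continue;
                double sgn = ((u + v + w) % 2) ? -1.0 : 1.0;
                double e = sgn * exy * Ez[w];
                for (int t1 = 0; t1 < dimb; ++t1)
                  for (int t2 = 0; t2 < dimb; ++t2)
                    for (int t3 = 0; t3 < dimb; ++t3)
                      Theta(((size_t)t1 * dimb + t2) * dimb + t3, cdi) +=
                        e * R0[rid(t1 + u, t2 + v, t3 + w)];
              }
            }
          }
        }
      // bra Hermite contraction
      for (int a = 0; a < B.nca; ++a)
        for (int b = 0; b < B.ncb; ++b) {
          int abi = a * B.ncb + b;
          int tx = ca[a].x + cb[b].x, ty = ca[a].y + cb[b].y, tz = ca[a].z + cb[b].z;
          const double* Ex = &pb.Ex[(size_t)(ca[a].x * (lb + 1) + cb[b].x) * tdb];
          const double* Ey = &pb.Ey[(size_t)(ca[a].y * (lb + 1) + cb[b].y) * tdb];
          const double* Ez = &pb.Ez[(size_t)(ca[a].z * (lb + 1) + cb[b].z) * tdb];
          for (int t1 = 0; t1 <= tx; ++t1) {
            if (Ex[t1] == 0.0) continue;
            for (int t2 = 0; t2 <= ty; ++t2) {
              if (Ey[t2] == 0.0) continue;
              double exy = Ex[t1] * Ey[t2];
              for (int t3 = 0; t3 <= tz; ++t3) {
                if (Ez[t3] == 0.0) continue;
                double e = exy * Ez[t3];
                const double* th = Theta.colptr(0) +
                  ((size_t)t1 * dimb + t2) * dimb + t3;
                for (int cdi = 0; cdi < ncd; ++cdi)
                  out(abi, cdi) += pref * e * th[(size_t)cdi * Theta.n_rows];
              }
            }
          }
        }
    }
  return out;
}

static arma::mat eri_block(const ShellPair& B, const ShellPair& K) {
  return B.WW * eri_block_cart(B, K) * K.WW.t();
}

static void set_schwarz(std::vector<ShellPair>& ps) {
  for (ShellPair& p : ps) {
    arma::mat d = eri_block(p, p);
    p.q = std::sqrt(d.diag().max());
  }
}

static std::vector<ShellPair> ao_pairs(const std::vector<Shell>& sh) {
  std::vector<ShellPair> ps;
  for (size_t i = 0; i < sh.size(); ++i)
    for (size_t j = 0; j <= i; ++j) ps.push_back(make_pair(sh, i, j));
  set_schwarz(ps);
  return ps;
}

static std::vector<ShellPair> fit_singles(const std::vector<Shell>& sh) {
  std::vector<ShellPair> ps;
  for (size_t i = 0; i < sh.size(); ++i) ps.push_back(make_pair(sh, i, -1));
  set_schwarz(ps);
  return ps;
}

static std::vector<int> offsets(const std::vector<Shell>& sh) {
  std::vector<int> o(sh.size());
  int n = 0;
  for (size_t i = 0; i < sh.size(); ++i) { o[i] = n; n += sh[i].nf(); }
  return o;
}

// ------------------------------------------------------------- one-particle

// [[Rcpp::export]]
List cpp_overlap_kinetic(List shells) {
  std::vector<Shell> sh = parse_shells(shells);
  std::vector<int> off = offsets(sh);
  int n = basis_nf(sh);
  arma::mat S(n, n, arma::fill::zeros), T(n, n, arma::fill::zeros);
  std::vector<double> Ex, Ey, Ez;
  for (size_t I = 0; I < sh.size(); ++I)
    for (size_t J = 0; J <= I; ++J) {
      const Shell &A = sh[I], &Bs = sh[J];
      int la = A.l, lb = Bs.l;
      std::vector<CartComp> ca = cart_list(la), cb = cart_list(lb);
      arma::mat Sc(A.nc() * Bs.nc(), 1, arma::fill::zeros),
                Tc(A.nc() * Bs.nc(), 1, arma::fill::zeros);
      int jmax = lb + 2, tdim = la + jmax + 1;
      for (arma::uword ka = 0; ka < A.ex.n_elem; ++ka)
        for (arma::uword kb = 0; kb < Bs.ex.n_elem; ++kb) {
          double a = A.ex(ka), b = Bs.ex(kb), p = a + b;
          double cc = A.cf(ka) * Bs.cf(kb), sp = std::sqrt(M_PI / p);
          ecoef(la, jmax, a, b, A.R(0) - Bs.R(0), Ex);
          ecoef(la, jmax, a, b, A.R(1) - Bs.R(1), Ey);
          ecoef(la, jmax, a, b, A.R(2) - Bs.R(2), Ez);
          auto S1 = [&](const std::vector<double>& E, int i, int j) {
            if (j < 0) return 0.0;
            return E[(size_t)(i * (jmax + 1) + j) * tdim] * sp;
          };
          auto T1 = [&](const std::vector<double>& E, int i, int j) {
            double v = -2.0 * b * b * S1(E, i, j + 2) +
                       b * (2 * j + 1) * S1(E, i, j);
            if (j >= 2) v -= 0.5 * j * (j - 1) * S1(E, i, j - 2);
            return v;
          };
          for (int ia = 0; ia < A.nc(); ++ia)
            for (int ib = 0; ib < Bs.nc(); ++ib) {
              double sx = S1(Ex, ca[ia].x, cb[ib].x), sy = S1(Ey, ca[ia].y, cb[ib].y),
                     sz = S1(Ez, ca[ia].z, cb[ib].z);
              double tx = T1(Ex, ca[ia].x, cb[ib].x), ty = T1(Ey, ca[ia].y, cb[ib].y),
                     tz = T1(Ez, ca[ia].z, cb[ib].z);
              Sc(ia * Bs.nc() + ib, 0) += cc * sx * sy * sz;
              Tc(ia * Bs.nc() + ib, 0) += cc * (tx * sy * sz + sx * ty * sz + sx * sy * tz);
            }
        }
      arma::mat WW = arma::kron(A.W, Bs.W);
      arma::vec Sb = WW * Sc, Tb = WW * Tc;
      for (int fa = 0; fa < A.nf(); ++fa)
        for (int fb = 0; fb < Bs.nf(); ++fb) {
          int mu = off[I] + fa, nu = off[J] + fb;
          S(mu, nu) = S(nu, mu) = Sb(fa * Bs.nf() + fb);
          T(mu, nu) = T(nu, mu) = Tb(fa * Bs.nf() + fb);
        }
    }
  return List::create(_["S"] = S, _["T"] = T);
}

// charge-weighted point-charge potential matrix, positive Coulomb kernel:
// P_{mu nu} = sum_c q_c \int chi_mu(r) chi_nu(r) / |r - R_c| dr
// [[Rcpp::export]]
arma::mat cpp_attraction(List shells, arma::vec q, arma::mat pos) {
  std::vector<Shell> sh = parse_shells(shells);
  std::vector<int> off = offsets(sh);
  int n = basis_nf(sh);
  arma::mat V(n, n, arma::fill::zeros);
  if (q.n_elem == 0) return V;
  if (pos.n_rows != q.n_elem || pos.n_cols != 3) stop("point charge table malformed");
  std::vector<double> R0;
  for (size_t I = 0; I < sh.size(); ++I)
    for (size_t J = 0; J <= I; ++J) {
      ShellPair P = make_pair(sh, I, J);
      int la = P.la, lb = P.lb, tmax = la + lb, dim = tmax + 1;
      std::vector<CartComp> ca = cart_list(la), cb = cart_list(lb);
      arma::vec Vc(P.nca * P.ncb, arma::fill::zeros);
      for (const PrimPair& pp : P.pp) {
        double pref = 2.0 * M_PI / pp.p;
        for (arma::uword c = 0; c < q.n_elem; ++c) {
          arma::vec3 PC = {pp.P(0) - pos(c, 0), pp.P(1) - pos(c, 1), pp.P(2) - pos(c, 2)};
          rtensor(tmax, pp.p, PC(0), PC(1), PC(2), R0);
          auto rid = [&](int t, int u, int v) { return ((size_t)t * dim + u) * dim + v; };
          for (int ia = 0; ia < P.nca; ++ia)
            for (int ib = 0; ib < P.ncb; ++ib) {
              int tdb = la + lb + 1;
              const double* Ex = &pp.Ex[(size_t)(ca[ia].x * (lb + 1) + cb[ib].x) * tdb];
              const double* Ey = &pp.Ey[(size_t)(ca[ia].y * (lb + 1) + cb[ib].y) * tdb];
              const double* Ez = &pp.Ez[(size_t)(ca[ia].z * (lb + 1) + cb[ib].z) * tdb];
              double acc = 0.0;
              for (int t = 0; t <= ca[ia].x + cb[ib].x; ++t)
                for (int u = 0; u <= ca[ia].y + cb[ib].y; ++u)
                  for (int v = 0; v <= ca[ia].z + cb[ib].z; ++v)
                    acc += Ex[t] * Ey[u] * Ez[v] * R0[rid(t, u, v)];
              Vc(ia * P.ncb + ib) += pref * pp.c * q(c) * acc;
            }
        }
      }
      arma::vec Vb = P.WW * Vc;
      for (int fa = 0; fa < sh[I].nf(); ++fa)
        for (int fb = 0; fb < sh[J].nf(); ++fb) {
          int mu = off[I] + fa, nu = off[J] + fb;
          V(mu, nu) = V(nu, mu) = Vb(fa * sh[J].nf() + fb);
        }
    }
  return V;
}

// ------------------------------------------------------------- two-particle

// [[Rcpp::export]]
arma::mat cpp_metric2(List fit_shells) {
  std::vector<Shell> sh = parse_shells(fit_shells);
  std::vector<ShellPair> fs = fit_singles(sh);
  std::vector<int> off = offsets(sh);
  int n = basis_nf(sh);
  arma::mat J(n, n, arma::fill::zeros);
  for (size_t I = 0; I < fs.size(); ++I)
    for (size_t J2 = 0; J2 <= I; ++J2) {
      arma::mat B = eri_block(fs[I], fs[J2]);
      for (int fa = 0; fa < fs[I].nfa; ++fa)
        for (int fb = 0; fb < fs[J2].nfa; ++fb) {
          J(off[I] + fa, off[J2] + fb) = B(fa, fb);
          J(off[J2] + fb, off[I] + fa) = B(fa, fb);
        }
    }
  return J;
}

// 3-index tensor (mu nu | A) returned as (nao*nao) x nfit, row = mu + nu*nao
// [[Rcpp::export]]
arma::mat cpp_eri3(List ao_shells, List fit_shells, double thresh = 1e-14) {
  std::vector<Shell> ash = parse_shells(ao_shells);
  std::vector<Shell> fsh = parse_shells(fit_shells);
  std::vector<ShellPair> ap = ao_pairs(ash), fp = fit_singles(fsh);
  std::vector<int> aoff = offsets(ash), foff = offsets(fsh);
  int nao = basis_nf(ash), nfit = basis_nf(fsh);
  arma::mat B3((size_t)nao * nao, nfit, arma::fill::zeros);
  for (const ShellPair& P : ap)
    for (size_t F = 0; F < fp.size(); ++F) {
      if (P.q * fp[F].q < thresh) continue;
      arma::mat B = eri_block(P, fp[F]);
      int nfb = ash[P.j].nf();
      for (int fa = 0; fa < ash[P.i].nf(); ++fa)
        for (int fb = 0; fb < nfb; ++fb) {
          int mu = aoff[P.i] + fa, nu = aoff[P.j] + fb;
          for (int fc = 0; fc < fp[F].nfa; ++fc) {
            double v = B(fa * nfb + fb, fc);
            B3((size_t)mu + (size_t)nu * nao, foff[F] + fc) = v;
            B3((size_t)nu + (size_t)mu * nao, foff[F] + fc) = v;
          }
        }
    }
  return B3;
}

// full four-index tensor over packed AO pairs (i >= j), chemists' notation
// [[Rcpp::export]]
arma::mat cpp_eri4_packed(List ao_shells, double thresh = 1e-14) {
  std::vector<Shell> sh = parse_shells(ao_shells);
  std::vector<ShellPair> ap = ao_pairs(sh);
  std::vector<int> off = offsets(sh);
  int nao = basis_nf(sh);
  size_t npair = (size_t)nao * (nao + 1) / 2;
  arma::mat M(npair, npair, arma::fill::zeros);
  auto pk = [](int i, int j) { return (size_t)std::max(i, j) * (std::max(i, j) + 1) / 2 + std::min(i, j); };
  for (size_t P = 0; P < ap.size(); ++P)
    for (size_t Q = 0; Q <= P; ++Q) {
      if (ap[P].q * ap[Q].q < thresh) continue;
      arma::mat B = eri_block(ap[P], ap[Q]);
      const ShellPair &b = ap[P], &k = ap[Q];
      int nfb = sh[b.j].nf(), nfd = sh[k.j].nf();
      for (int fa = 0; fa < sh[b.i].nf(); ++fa)
        for (int fb = 0; fb < nfb; ++fb) {
          int mu = off[b.i] + fa, nu = off[b.j] + fb;
          if (nu > mu) continue;
          size_t r = pk(mu, nu);
          for (int fc = 0; fc < sh[k.i].nf(); ++fc)
            for (int fd = 0; fd < nfd; ++fd) {
              int lm = off[k.i] + fc, sg = off[k.j] + fd;
              if (sg > lm) continue;
              size_t cidx = pk(lm, sg);
              double v = B((size_t)fa * nfb + fb, (size_t)fc * nfd + fd);
              M(r, cidx) = v;
              M(cidx, r) = v;
            }
        }
    }
  return M;
}

// Coulomb matrix alone from the packed tensor (one matrix-vector product)
// [[Rcpp::export]]
arma::mat cpp_j_packed(const arma::mat& M, const arma::mat& D) {
  int n = D.n_rows;
  size_t npair = (size_t)n * (n + 1) / 2;
  if (M.n_rows != npair) stop("packed tensor does not match density dimension");
  auto pk = [](int i, int j) { return (size_t)std::max(i, j) * (std::max(i, j) + 1) / 2 + std::min(i, j); };
  arma::vec w(npair);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j <= i; ++j)
      w(pk(i, j)) = (i == j) ? D(i, j) : D(i, j) + D(j, i);
  arma::vec jv = M * w;
  arma::mat J(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j <= i; ++j) { J(i, j) = jv(pk(i, j)); J(j, i) = J(i, j); }
  return J;
}

// J and K from the packed four-index matrix and a symmetric density
// [[Rcpp::export]]
List cpp_jk_packed(const arma::mat& M, const arma::mat& D) {
  int n = D.n_rows;
  size_t npair = (size_t)n * (n + 1) / 2;
  if (M.n_rows != npair) stop("packed tensor does not match density dimension");
  auto pk = [](int i, int j) { return (size_t)std::max(i, j) * (std::max(i, j) + 1) / 2 + std::min(i, j); };
  arma::vec w(npair);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j <= i; ++j)
      w(pk(i, j)) = (i == j) ? D(i, j) : D(i, j) + D(j, i);
  arma::vec jv = M * w;
  arma::mat J(n, n), K(n, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j <= i; ++j) { J(i, j) = jv(pk(i, j)); J(j, i) = J(i, j); }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j <= i; ++j) {
      double acc = 0.0;
      for (int k = 0; k < n; ++k) {
        size_t rik = pk(i, k);
        for (int l = 0; l < n; ++l) acc += M(rik, pk(j, l)) * D(k, l);
      }
      K(i, j) = K(j, i) = acc;
    }
  return List::create(_["J"] = J, _["K"] = K);
}

// exchange from the packed tensor via (natural) orbitals:
// K_{nu sig} = sum_i n_i (i nu|i sig), built per nu with contiguous column
// gathers and a dense half-transform
// [[Rcpp::export]]
arma::mat cpp_k_occ_packed(const arma::mat& M, const arma::mat& Cocc,
                           const arma::vec& occ) {
  int n = Cocc.n_rows, no = Cocc.n_cols;
  size_t npair = (size_t)n * (n + 1) / 2;
  if (M.n_rows != npair) stop("packed tensor does not match orbital dimension");
  auto pk = [](int i, int j) { return (size_t)std::max(i, j) * (std::max(i, j) + 1) / 2 + std::min(i, j); };
  arma::mat K(n, n, arma::fill::zeros);
  arma::mat Mnu(npair, n);
  for (int nu = 0; nu < n; ++nu) {
    for (int mu = 0; mu < n; ++mu) Mnu.col(mu) = M.col(pk(mu, nu));
    arma::mat Gt = Mnu * Cocc; // (npair x no): (i nu | P)
    for (int sig = 0; sig <= nu; ++sig) {
      double acc = 0.0;
      for (int i = 0; i < no; ++i) {
        double s = 0.0;
        const double* g = Gt.colptr(i);
        for (int lam = 0; lam < n; ++lam)
          s += Cocc(lam, i) * g[pk(lam, sig)];
        acc += occ(i) * s;
      }
      K(nu, sig) = K(sig, nu) = acc;
    }
  }
  return K;
}

// direct Coulomb contraction: J_bra[mu nu] = sum_{lam sig} (mu nu|lam sig) D_ket[lam sig]
// with Schwarz x density prescreening
// [[Rcpp::export]]
arma::mat cpp_coulomb_cross(List bra_shells, List ket_shells, const arma::mat& Dket,
                            double thresh = 1e-10) {
  std::vector<Shell> bsh = parse_shells(bra_shells);
  std::vector<Shell> ksh = parse_shells(ket_shells);
  std::vector<ShellPair> bp = ao_pairs(bsh), kp = ao_pairs(ksh);
  std::vector<int> boff = offsets(bsh), koff = offsets(ksh);
  int nb = basis_nf(bsh);
  if ((int)Dket.n_rows != basis_nf(ksh)) stop("ket density dimension mismatch");
  arma::mat J(nb, nb, arma::fill::zeros);
  // per ket pair density bound
  std::vector<double> dmax(kp.size());
  for (size_t Q = 0; Q < kp.size(); ++Q) {
    const ShellPair& k = kp[Q];
    arma::mat blk = Dket.submat(koff[k.i], koff[k.j],
                                koff[k.i] + ksh[k.i].nf() - 1,
                                koff[k.j] + ksh[k.j].nf() - 1);
    dmax[Q] = arma::abs(blk).max();
  }
  for (const ShellPair& b : bp) {
    int nfb = bsh[b.j].nf();
    arma::vec acc(b.nfa * nfb, arma::fill::zeros);
    for (size_t Q = 0; Q < kp.size(); ++Q) {
      const ShellPair& k = kp[Q];
      double fac = (k.i == k.j) ? 1.0 : 2.0;
      if (b.q * k.q * dmax[Q] * fac < thresh) continue;
      arma::mat B = eri_block(b, k);
      int nfd = ksh[k.j].nf();
      for (int fc = 0; fc < ksh[k.i].nf(); ++fc)
        for (int fd = 0; fd < nfd; ++fd) {
          double d = Dket(koff[k.i] + fc, koff[k.j] + fd);
          if (k.i != k.j) d += Dket(koff[k.j] + fd, koff[k.i] + fc);
          if (d == 0.0) continue;
          acc += d * B.col((size_t)fc * nfd + fd);
        }
    }
    for (int fa = 0; fa < bsh[b.i].nf(); ++fa)
      for (int fb = 0; fb < nfb; ++fb) {
        int mu = boff[b.i] + fa, nu = boff[b.j] + fb;
        J(mu, nu) = J(nu, mu) = acc(fa * nfb + fb);
      }
  }
  return J;
}

// packed cross four-index tensor between two particle classes:
// rows = bra pairs (mu >= nu), cols = ket pairs (lam >= sig)
// [[Rcpp::export]]
arma::mat cpp_eri_cross_packed(List bra_shells, List ket_shells,
                               double thresh = 1e-14) {
  std::vector<Shell> bsh = parse_shells(bra_shells);
  std::vector<Shell> ksh = parse_shells(ket_shells);
  std::vector<ShellPair> bp = ao_pairs(bsh), kp = ao_pairs(ksh);
  std::vector<int> boff = offsets(bsh), koff = offsets(ksh);
  int nb = basis_nf(bsh), nk = basis_nf(ksh);
  size_t npb = (size_t)nb * (nb + 1) / 2, npk = (size_t)nk * (nk + 1) / 2;
  arma::mat M(npb, npk, arma::fill::zeros);
  auto pk = [](int i, int j) { return (size_t)std::max(i, j) * (std::max(i, j) + 1) / 2 + std::min(i, j); };
  for (const ShellPair& b : bp)
    for (const ShellPair& k : kp) {
      if (b.q * k.q < thresh) continue;
      arma::mat B = eri_block(b, k);
      int nfb = bsh[b.j].nf(), nfd = ksh[k.j].nf();
      for (int fa = 0; fa < bsh[b.i].nf(); ++fa)
        for (int fb = 0; fb < nfb; ++fb) {
          int mu = boff[b.i] + fa, nu = boff[b.j] + fb;
          if (nu > mu) continue;
          size_t r = pk(mu, nu);
          for (int fc = 0; fc < ksh[k.i].nf(); ++fc)
            for (int fd = 0; fd < nfd; ++fd) {
              int lm = koff[k.i] + fc, sg = koff[k.j] + fd;
              if (sg > lm) continue;
              M(r, pk(lm, sg)) = B((size_t)fa * nfb + fb, (size_t)fc * nfd + fd);
            }
        }
    }
  return M;
}

// ------------------------------------------------------------ grid evaluation

// basis functions evaluated on points: (npts x nao)
// [[Rcpp::export]]
arma::mat cpp_eval_basis(List shells, const arma::mat& pts) {
  std::vector<Shell> sh = parse_shells(shells);
  int nao = basis_nf(sh);
  arma::mat out(pts.n_rows, nao, arma::fill::zeros);
  int col = 0;
  for (const Shell& S : sh) {
    std::vector<CartComp> cc = cart_list(S.l);
    arma::mat cart(pts.n_rows, S.nc());
    for (arma::uword p = 0; p < pts.n_rows; ++p) {
      double x = pts(p, 0) - S.R(0), y = pts(p, 1) - S.R(1), z = pts(p, 2) - S.R(2);
      double r2 = x * x + y * y + z * z, rad = 0.0;
      for (arma::uword k = 0; k < S.ex.n_elem; ++k)
        rad += S.cf(k) * std::exp(-S.ex(k) * r2);
      for (int m = 0; m < S.nc(); ++m)
        cart(p, m) = std::pow(x, cc[m].x) * std::pow(y, cc[m].y) * std::pow(z, cc[m].z) * rad;
    }
    arma::mat fin = cart * S.W.t();
    out.cols(col, col + S.nf() - 1) = fin;
    col += S.nf();
  }
  return out;
}
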