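#include <Rcpp.h>
using namespace Rcpp;

// Direct form II transposed IIR filter with explicit initial state.
// b, a: filter coefficients (a[0] == 1 expected after normalisation),
// zi: initial conditions of length max(len(a), len(b)) - 1.
// [[Rcpp::export]]
NumericVector filter_df2t(NumericVector b, NumericVector a,
                          NumericVector x, NumericVector zi) {
  int nb = b.size(), na = a.size();
  int n = std::max(nb, na);
  std::vector<double> bb(n, 0.0), aa(n, 0.0);
  double a0 = a[0];
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a0;
  std::vector<double> z(n - 1, 0.0);
  for (int i = 0; i < (int)z.size() && i < zi.size(); ++i) z[i] = zi[i];
  int m = x.size();
  NumericVector y(m);
  const double *px = REAL(x);
  double *py = REAL(y);
  double *pz = z.data();
  const double *pb = bb.data(), *pa = aa.data();
  for (int t = 0; t < m; ++t) {
    double xt = px[t];
    double yt = pb[0] * xt + (n > 1 ? pz[0] : 0.0);
    for (int k = 0; k < n - 2; ++k)
      pz[k] = pb[k + 1] * xt + pz[k + 1] - pa[k + 1] * yt;
    if (n > 1)
      pz[n - 2] = pb[n - 1] * xt - pa[n - 1] * yt;
    py[t] = yt;
  }
  return y;
}

static inline double wrap_angle(double a) {
  while (a > M_PI) a -= 2.0 * M_PI;
  while (a < -M_PI) a += 2.0 * M_PI;
  return a;
}

// Two-state (pause/walk) correlated random walk inside a rectangular arena.
// Pause and walk durations are exponential; each walk bout draws a gamma
// speed; heading evolves as a random walk during bouts and is blended
// toward the nearest wall tangent (thigmotaxis) within `margin` of a wall.
// A step that would leave the arena steers along the wall instead.
// Uses R's RNG, so results are governed by set.seed().
// [[Rcpp::export]]
List sim_crw(int n_frames, double fps,
             double arena_l, double arena_w,
             double pause_mean_s, double walk_mean_s,
             double speed_mean, double speed_shape,
             double turning_sd, double thigmo_weight, double margin_mm) {
  RNGScope scope;
  NumericVector x(n_frames), y(n_frames), heading(n_frames);
  IntegerVector bout_id(n_frames); // 0 = pause, k = k-th walk bout
  std::vector<double> bout_speed_v;
  std::vector<int> bout_start_v, bout_end_v;

  // start at a uniform random interior position, random heading
  double px = R::runif(0.05 * arena_l, 0.95 * arena_l);
  double py = R::runif(0.05 * arena_w, 0.95 * arena_w);
  double th = R::runif(-M_PI, M_PI);

  // durations capped at the trial length to avoid integer overflow in the
  // degenerate pause_mean -> Inf limit
  auto draw_frames = [&](double mean_s) {
    double d = std::floor(R::rexp(mean_s) * fps + 0.5);
    d = std::min(d, (double)(n_frames + 1));
    return std::max(1, (int)d);
  };
  bool walking = false;
  int frames_left = draw_frames(pause_mean_s);
  double bout_speed = 0.0;
  int cur_bout = 0;

  for (int t = 0; t < n_frames; ++t) {
    if (frames_left == 0) {
      if (walking && cur_bout > 0) bout_end_v.push_back(t - 1);
      walking = !walking;
      if (walking) {
        frames_left = draw_frames(walk_mean_s);
        bout_speed = R::rgamma(speed_shape, speed_mean / speed_shape);
        th = R::runif(-M_PI, M_PI); // new bout starts in a fresh direction
        ++cur_bout;
        bout_speed_v.push_back(bout_speed);
        bout_start_v.push_back(t);
      } else {
        frames_left = draw_frames(pause_mean_s);
      }
    }
    if (walking) {
      th = wrap_angle(th + R::norm_rand() * turning_sd);
      // thigmotaxis: near a wall, blend heading toward the wall tangent
      double dl = px, dr = arena_l - px, db = py, dt_ = arena_w - py;
      double dmin = std::min(std::min(dl, dr), std::min(db, dt_));
      if (dmin < margin_mm && thigmo_weight > 0.0) {
        double tangent;
        if (dmin == dl || dmin == dr) tangent = M_PI / 2.0; // vertical wall
        else tangent = 0.0;                                  // horizontal wall
        // pick the tangent direction closest to the current heading
        double t1 = tangent, t2 = wrap_angle(tangent + M_PI);
        double d1 = std::fabs(wrap_angle(th - t1));
        double d2 = std::fabs(wrap_angle(th - t2));
        double target = (d1 <= d2) ? t1 : t2;
        double w = thigmo_weight * (1.0 - dmin / margin_mm);
        double cx = (1.0 - w) * std::cos(th) + w * std::cos(target);
        double cy = (1.0 - w) * std::sin(th) + w * std::sin(target);
        if (cx != 0.0 || cy != 0.0) th = std::atan2(cy, cx);
      }
      double step = bout_speed / fps;
      double nx = px + step * std::cos(th);
      double ny = py + step * std::sin(th);
      if (nx < 0.0 || nx > arena_l || ny < 0.0 || ny > arena_w) {
        // steer along the blocked wall, keeping the unblocked component's sign
        double vx = std::cos(th), vy = std::sin(th);
        if (nx < 0.0 || nx > arena_l) { vx = 0.0; }
        if (ny < 0.0 || ny > arena_w) { vy = 0.0; }
        if (vx == 0.0 && vy == 0.0) { // cornered: reverse
          th = wrap_angle(th + M_PI);
        } else {
          th = std::atan2(vy, vx);
        }
        nx = px + step * std::cos(th);
        ny = py + step * std::sin(th);
        nx = std::min(std::max(nx, 0.0), arena_l);
        ny = std::min(std::max(ny, 0.0), arena_w);
      }
      px = nx; py = ny;
    }
    x[t] = px; y[t] = py; heading[t] = th;
    bout_id[t] = walking ? cur_bout : 0;
    --frames_left;
  }
  if (walking && cur_bout > 0) bout_end_v.push_back(n_frames - 1);

  return List::create(
    _["x"] = x, _["y"] = y, _["heading"] = heading,
    _["bout_id"] = bout_id,
    _["bout_start"] = IntegerVector(bout_start_v.begin(), bout_start_v.end()),
    _["bout_end"] = IntegerVector(bout_end_v.begin(), bout_end_v.end()),
    _["bout_speed"] = NumericVector(bout_speed_v.begin(), bout_speed_v.end()));
}
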