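// ORCA-style reciprocal collision avoidance in 3D.
//
// For each agent, every neighbour induces a half-space constraint in
// velocity space derived from the truncated velocity-obstacle cone; the
// collision-free velocity closest (2-norm) to the preferred velocity is
// found by an incremental linear program over the intersection of the
// half-spaces and the max-speed ball.  Responsibility for avoidance is
// shared reciprocally (each agent takes half the correction); static
// obstacles are spheres for which the agent takes the full correction.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const double ORCA_EPS = 1e-10;

struct Vec3 {
  double x, y, z;
  Vec3(double x_ = 0, double y_ = 0, double z_ = 0) : x(x_), y(y_), z(z_) {}
};

static inline Vec3 operator+(const Vec3 &a, const Vec3 &b) { return Vec3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline Vec3 operator-(const Vec3 &a, const Vec3 &b) { return Vec3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline Vec3 operator*(double s, const Vec3 &a) { return Vec3(s * a.x, s * a.y, s * a.z); }
static inline double dot(const Vec3 &a, const Vec3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline double absSq(const Vec3 &a) { return dot(a, a); }
static inline double norm(const Vec3 &a) { return std::sqrt(absSq(a)); }
static inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline Vec3 normalize(const Vec3 &a) {
  double n = norm(a);
  return n > 0 ? (1.0 / n) * a : Vec3();
}

// deterministic unit vector perpendicular to a (for degenerate on-axis cases)
static inline Vec3 perpendicular(const Vec3 &a) {
  Vec3 p = cross(a, Vec3(0, 0, 1));
  if (absSq(p) < 1e-12) p = cross(a, Vec3(1, 0, 0));
  return normalize(p);
}

// Feasible velocities v satisfy dot(v - point, normal) >= 0.
struct Plane {
  Vec3 point, normal;
};

struct Line {
  Vec3 point, direction;
};

// Minimise |v - optV| on the segment of `line` inside the radius ball and
// the first planeNo half-spaces.
static bool linearProgram1(const std::vector<Plane> &planes, size_t planeNo,
                           const Line &line, double radius, const Vec3 &optV,
                           Vec3 &result) {
  const double dotProduct = dot(line.point, line.direction);
  const double discriminant = dotProduct * dotProduct + radius * radius - absSq(line.point);
  if (discriminant < 0.0) return false;  // line misses the ball

  const double sqrtDiscriminant = std::sqrt(discriminant);
  double tLeft = -dotProduct - sqrtDiscriminant;
  double tRight = -dotProduct + sqrtDiscriminant;

  for (size_t i = 0; i < planeNo; ++i) {
    const double numerator = dot(planes[i].point - line.point, planes[i].normal);
    const double denominator = dot(line.direction, planes[i].normal);
    if (denominator * denominator <= ORCA_EPS) {
      if (numerator > 0.0) return false;  // line parallel to and outside plane i
      continue;
    }
    const double t = numerator / denominator;
    if (denominator >= 0.0) tLeft = std::max(tLeft, t);
    else tRight = std::min(tRight, t);
    if (tLeft > tRight) return false;
  }

  double t = dot(line.direction, optV - line.point);
  t = std::min(std::max(t, tLeft), tRight);
  result = line.point + t * line.direction;
  return true;
}

// Minimise |v - optV| on the disc where plane planeNo cuts the ball,
// subject to the first planeNo half-spaces.
static bool linearProgram2(const std::vector<Plane> &planes, size_t planeNo,
                           double radius, const Vec3 &optV, Vec3 &result) {
  const double planeDist = dot(planes[planeNo].point, planes[planeNo].normal);
  const double planeDistSq = planeDist * planeDist;
  const double radiusSq = radius * radius;
  if (planeDistSq > radiusSq) return false;  // plane misses the ball

  const double planeRadiusSq = radiusSq - planeDistSq;
  const Vec3 planeCenter = planeDist * planes[planeNo].normal;

  // project optV onto the plane, clamp to the disc
  result = optV + dot(planes[planeNo].point - optV, planes[planeNo].normal) * planes[planeNo].normal;
  if (absSq(result) > radiusSq) {
    const Vec3 planeResult = result - planeCenter;
    const double planeResultLengthSq = absSq(planeResult);
    result = planeCenter + std::sqrt(planeRadiusSq / planeResultLengthSq) * planeResult;
  }

  for (size_t i = 0; i < planeNo; ++i) {
    if (dot(planes[i].normal, planes[i].point - result) > 0.0) {
      // project onto the intersection line of plane i and plane planeNo
      Vec3 crossProduct = cross(planes[i].normal, planes[planeNo].normal);
      if (absSq(crossProduct) <= ORCA_EPS) return false;
      Line line;
      line.direction = normalize(crossProduct);
      const Vec3 lineNormal = cross(line.direction, planes[planeNo].normal);
      line.point = planes[planeNo].point +
        (dot(planes[i].point - planes[planeNo].point, planes[i].normal) /
         dot(lineNormal, planes[i].normal)) * lineNormal;
      if (!linearProgram1(planes, i, line, radius, optV, result)) return false;
    }
  }
  return true;
}

// Minimise |v - optV| over the intersection of all half-spaces and the
// max-speed ball.  Returns planes.size() on success, else the index of the
// first failing constraint.
static size_t linearProgram3(const std::vector<Plane> &planes, double radius,
                             const Vec3 &optV, Vec3 &result) {
  if (absSq(optV) > radius * radius) result = radius * normalize(optV);
  else result = optV;

  for (size_t i = 0; i < planes.size(); ++i) {
    if (dot(planes[i].normal, planes[i].point - result) > 0.0) {
      const Vec3 tempResult = result;
      if (!linearProgram2(planes, i, radius, optV, result)) {
        result = tempResult;
        return i;
      }
    }
  }
  return planes.size();
}

// Half-space constraint induced on agent velocity v_i by a neighbour
// (reciprocal = true shares the correction; false takes it fully, used for
// static obstacles).  dt resolves already-colliding pairs.
static Plane makePlane(const Vec3 &relPos, const Vec3 &relVel, const Vec3 &vi,
                       double combinedRadius, double invTimeHorizon,
                       double invTimeStep, bool reciprocal) {
  const double distSq = absSq(relPos);
  const double combinedRadiusSq = combinedRadius * combinedRadius;
  Plane plane;
  Vec3 u;

  if (distSq > combinedRadiusSq) {
    // no current collision: truncated cone in relative velocity space
    const Vec3 w = relVel - invTimeHorizon * relPos;
    const double wLengthSq = absSq(w);
    const double dotProduct = dot(w, relPos);

    if (dotProduct < 0.0 && dotProduct * dotProduct > combinedRadiusSq * wLengthSq) {
      // project on the cut-off sphere
      const double wLength = std::sqrt(wLengthSq);
      const Vec3 unitW = wLength > 0 ? (1.0 / wLength) * w : Vec3(1, 0, 0);
      plane.normal = unitW;
      u = (combinedRadius * invTimeHorizon - wLength) * unitW;
    } else {
      // project on the cone surface
      const double a = distSq;
      const double b = dot(relPos, relVel);
      const double c = absSq(relVel) - absSq(cross(relPos, relVel)) / (distSq - combinedRadiusSq);
      const double disc = std::max(b * b - a * c, 0.0);
      const double t = (b + std::sqrt(disc)) / a;
      const Vec3 ww = relVel - t * relPos;
      const double wwLength = norm(ww);
      Vec3 unitWW;
      if (wwLength > 1e-12) {
        unitWW = (1.0 / wwLength) * ww;
      } else {
        // relative velocity exactly on the cone axis: push perpendicular to
        // the cone surface (deterministic lateral choice), i.e. the lateral
        // direction tilted back by the half-opening angle
        const double dist = std::sqrt(distSq);
        const double sinTheta = combinedRadius / dist;
        const double cosTheta = std::sqrt(std::max(1.0 - sinTheta * sinTheta, 0.0));
        unitWW = cosTheta * perpendicular(relPos) - (sinTheta / dist) * relPos;
      }
      plane.normal = unitWW;
      u = (combinedRadius * t - wwLength) * unitWW;
    }
  } else {
    // already colliding: push apart within one time step
    const Vec3 w = relVel - invTimeStep * relPos;
    const double wLength = norm(w);
    // coincident push-apart direction defaults to away from the neighbour
    const Vec3 unitW = wLength > 1e-12 ? (1.0 / wLength) * w
                       : (absSq(relPos) > 1e-18 ? normalize(-1.0 * relPos)
                                                : Vec3(1, 0, 0));
    plane.normal = unitW;
    u = (combinedRadius * invTimeStep - wLength) * unitW;
  }

  plane.point = vi + (reciprocal ? 0.5 : 1.0) * u;
  return plane;
}

// [[Rcpp::export(name = ".orca_resolve")]]
List orca_resolve(NumericMatrix positions, NumericMatrix velocities,
                  NumericMatrix preferred, double agentRadius,
                  double timeHorizon, double dt, double maxSpeed,
                  int policy,  // 0 = zero_velocity, 1 = halve_step
                  NumericMatrix obstaclePositions, NumericVector obstacleRadii) {
  const int n = positions.nrow();
  const int nObs = obstaclePositions.nrow();
  NumericMatrix newVel(n, 3);
  LogicalVector infeasible(n);

  // neighbour cull distance: beyond this no constraint can be active
  const double cull = 2.0 * maxSpeed * timeHorizon + 2.0 * agentRadius;
  const double cullSq = cull * cull;

  for (int i = 0; i < n; ++i) {
    const Vec3 pi(positions(i, 0), positions(i, 1), positions(i, 2));
    const Vec3 vi(velocities(i, 0), velocities(i, 1), velocities(i, 2));
    const Vec3 vPref(preferred(i, 0), preferred(i, 1), preferred(i, 2));

    double localDt = dt;
    Vec3 result;
    bool ok = false;
    int attempts = (policy == 1) ? 4 : 1;

    for (int attempt = 0; attempt < attempts && !ok; ++attempt) {
      std::vector<Plane> planes;
      const double invTimeHorizon = 1.0 / timeHorizon;
      const double invTimeStep = 1.0 / localDt;

      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        const Vec3 pj(positions(j, 0), positions(j, 1), positions(j, 2));
        const Vec3 relPos = pj - pi;
        if (absSq(relPos) > cullSq) continue;
        const Vec3 vj(velocities(j, 0), velocities(j, 1), velocities(j, 2));
        planes.push_back(makePlane(relPos, vi - vj, vi, 2.0 * agentRadius,
                                   invTimeHorizon, invTimeStep, true));
      }
      for (int j = 0; j < nObs; ++j) {
        const Vec3 pj(obstaclePositions(j, 0), obstaclePositions(j, 1), obstaclePositions(j, 2));
        const Vec3 relPos = pj - pi;
        const double rr = agentRadius + obstacleRadii[j];
        if (absSq(relPos) > (maxSpeed * timeHorizon + rr) * (maxSpeed * timeHorizon + rr)) continue;
        planes.push_back(makePlane(relPos, vi, vi, rr,
                                   invTimeHorizon, invTimeStep, false));
      }

      ok = (linearProgram3(planes, maxSpeed, vPref, result) == planes.size());
      if (!ok) localDt *= 0.5;  // halve_step policy retries with a smaller step
    }

    if (!ok) {
      infeasible[i] = true;
      result = Vec3();  // zero velocity fallback
    }
    newVel(i, 0) = result.x;
    newVel(i, 1) = result.y;
    newVel(i, 2) = result.z;
  }

  return List::create(Named("velocities") = newVel,
                      Named("infeasible") = infeasible);
}
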