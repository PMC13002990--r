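/* Compiled right-hand side of the alcohol-marker ODE system.
 *
 * Mirrors the R implementation (modelRHS in R/model.R) exactly; the tests
 * assert agreement between the two. Parameters, derived volumes and the
 * piecewise-constant segment inputs are passed through the single parms
 * vector (see rhs_parms_vector in R/simulate.R for the layout).
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#define NPARMS 46
static double parms[NPARMS];

/* parameter layout, matching rhs_parms_vector() */
enum {
  VmaxGastric, KmGastric, k_kcalscaling, km_kcal, n_kcal,
  k_poolIn, k_poolOut, VmaxADHSto, KmADHSto, k_EtOHuptake,
  k_equalize, k_equalize_liver, VmaxADH, VmaxCYP2E1, KmADH,
  KmCYP2E1, k_food_clearance, k_acetate, k_blood_plasma_ratio, k_urine_water,
  k_basal_vasopressin, k_vasopressin_BAC, k_clearance_vasopressin,
  k_kidney_permability, VmaxEtG, KmEtG, VmaxEtS, KmEtS,
  k_EtG_urine, k_EtS_urine, k_PEth, k_PEth_clearance, k_PEth_bind,
  k_PEth_release,
  /* derived volumes (dL) */
  iV_blood, iV_bc, iV_bp, iV_pp, iV_liver, iTBW,
  /* segment inputs */
  iVolDrinkPerTime, iKcalLiquidPerVol, iEtOHConc, iMealKcalPerMin,
  /* options */
  iFoodFactor, iVolStomach0
};

/* state layout, matching stateNames() + auditNames() */
enum {
  Vol_Stomach, Kcal_Liquid, Kcal_remain, MaxKcal_Solid, Kcal_Solid,
  EtOH_Pool, ConcEtOH_Stomach, MassEtOH_Intestines,
  BloodConcCentral, BloodConcPeripheral, TissueConc, LiverConc,
  LiverEtG, PeripheralEtG, LiverEtS, PeripheralEtS,
  Plasma_Acetate, TissueExtraWater, Vasopressin,
  UrineMassEtOH, UrineVolume, UrineMassEtG, UrineMassEtS,
  PEth, PEth_Bound, timeElapsed,
  cumIngested, cumElimStoADH, cumElimADH, cumElimCYP2E1,
  cumEtGsynth, cumEtSsynth, cumTissueNet, cumVoidedEtOH,
  NSTATE
};

void alcotwin_initmod(void (*odeparms)(int *, double *)) {
  int n = NPARMS;
  odeparms(&n, parms);
}

void alcotwin_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip) {
  const double dens = 789000.0; /* ethanol, mg per L of pure ethanol */
  double V_bc = parms[iV_bc], V_bp = parms[iV_bp], V_pp = parms[iV_pp];
  double V_liver = parms[iV_liver];
  double V_tissue = parms[iTBW] - parms[iV_blood] - V_liver + y[TissueExtraWater];

  /* gastric emptying */
  double vol_change = y[Vol_Stomach] - parms[iVolStomach0];
  if (vol_change < 0) vol_change = 0;
  double x = y[Kcal_Liquid] / parms[k_kcalscaling];
  double xn = pow(x, parms[n_kcal]);
  double kmn = pow(parms[km_kcal], parms[n_kcal]);
  double kcal_eff = 1.0 - xn / (xn + kmn);
  double r_vol_empty = parms[VmaxGastric] * vol_change /
    (vol_change + parms[KmGastric]) * kcal_eff;
  double dVol = parms[iVolDrinkPerTime] - r_vol_empty;
  double kcal_in = parms[iVolDrinkPerTime] * parms[iKcalLiquidPerVol];

  /* stomach ethanol: drink inflow, emptying, mucosal pool, gastric ADH */
  double r_EtOH_in = parms[iVolDrinkPerTime] * parms[iEtOHConc] * dens;
  double C_sto = y[ConcEtOH_Stomach];
  double M_sto = C_sto * 10.0 * y[Vol_Stomach];
  double r_empty_EtOH = r_vol_empty * 10.0 * C_sto;
  double r_sto_ADH = parms[VmaxADHSto] * C_sto / (C_sto + parms[KmADHSto]);
  double r_pool_in = parms[k_poolIn] * M_sto;
  double r_pool_out = parms[k_poolOut] * y[EtOH_Pool];
  double dM_sto = r_EtOH_in - r_empty_EtOH - r_sto_ADH - r_pool_in + r_pool_out;

  /* circulation */
  double r_uptake = y[MassEtOH_Intestines] * parms[k_EtOHuptake];
  double C_c = y[BloodConcCentral], C_p = y[BloodConcPeripheral];
  double r_circ = parms[k_equalize] * (C_c - C_p);
  double r_liver = parms[k_equalize_liver] * (C_p - y[LiverConc]);
  double r_tissue_per = C_p - y[TissueConc];

  /* urine transport */
  double r_tissueurine = y[TissueExtraWater] / y[Vasopressin] * parms[k_urine_water];
  double r_urine = r_tissueurine * (C_p * V_bp) / V_pp + 0.01 * C_p;
  double r_urinereturn = parms[k_kidney_permability] * y[Vasopressin] *
    (y[UrineMassEtOH] / y[UrineVolume] - C_p * V_bp / V_pp) * y[UrineVolume];

  /* hepatic elimination and conjugation */
  double C_l = y[LiverConc];
  double food = (y[Kcal_Solid] > 0) ? parms[iFoodFactor] : 1.0;
  double r_elim_ADH = parms[VmaxADH] * C_l / (C_l + parms[KmADH]) * food;
  double r_elim_CYP = parms[VmaxCYP2E1] * C_l / (C_l + parms[KmCYP2E1]) * food;
  double r_elim = r_elim_ADH + r_elim_CYP;
  double r_EtG = parms[VmaxEtG] * C_l / (C_l + parms[KmEtG]);
  double r_EtS = parms[VmaxEtS] * C_l / (C_l + parms[KmEtS]);
  double r_EtG_lp = y[LiverEtG] - y[PeripheralEtG];
  double r_EtS_lp = y[LiverEtS] - y[PeripheralEtS];
  double r_EtG_urine = parms[k_EtG_urine] * y[PeripheralEtG];
  double r_EtS_urine = parms[k_EtS_urine] * y[PeripheralEtS];

  ydot[Vol_Stomach] = dVol;
  ydot[Kcal_Liquid] = kcal_in;
  ydot[Kcal_remain] = kcal_in - r_vol_empty * y[Kcal_remain] / y[Vol_Stomach];
  ydot[MaxKcal_Solid] = parms[iMealKcalPerMin];
  ydot[Kcal_Solid] = parms[iMealKcalPerMin] - parms[k_food_clearance] * y[Kcal_Solid];
  ydot[EtOH_Pool] = r_pool_in - r_pool_out;
  ydot[ConcEtOH_Stomach] = (dM_sto - C_sto * 10.0 * dVol) / (10.0 * y[Vol_Stomach]);
  ydot[MassEtOH_Intestines] = r_empty_EtOH - r_uptake;
  ydot[BloodConcCentral] = r_uptake / V_bc - r_circ;
  ydot[BloodConcPeripheral] = r_circ * (V_bc / V_bp) - r_tissue_per - r_liver +
    (-r_urine + r_urinereturn) / V_bp;
  ydot[TissueConc] = r_tissue_per * V_bp / V_tissue;
  ydot[LiverConc] = r_liver * V_bp / V_liver - r_elim - r_EtG - r_EtS;
  ydot[LiverEtG] = r_EtG - r_EtG_lp;
  ydot[PeripheralEtG] = r_EtG_lp * V_liver / V_bp - r_EtG_urine;
  ydot[LiverEtS] = r_EtS - r_EtS_lp;
  ydot[PeripheralEtS] = r_EtS_lp * V_liver / V_bp - r_EtS_urine;
  ydot[Plasma_Acetate] = parms[k_acetate] *
    (r_elim * V_liver / V_pp - y[Plasma_Acetate]);
  ydot[TissueExtraWater] = r_vol_empty * 10.0 - r_tissueurine;
  ydot[Vasopressin] = parms[k_basal_vasopressin] /
    (1.0 + parms[k_vasopressin_BAC] * C_p) -
    y[Vasopressin] * parms[k_clearance_vasopressin];
  ydot[UrineMassEtOH] = r_urine - r_urinereturn;
  ydot[UrineVolume] = 0.01 + r_tissueurine;
  ydot[UrineMassEtG] = r_EtG_urine * V_bp;
  ydot[UrineMassEtS] = r_EtS_urine * V_bp;
  ydot[PEth] = parms[k_PEth] * C_p - parms[k_PEth_clearance] * y[PEth] -
    parms[k_PEth_bind] * y[PEth] + parms[k_PEth_release] * y[PEth_Bound];
  ydot[PEth_Bound] = parms[k_PEth_bind] * y[PEth] -
    parms[k_PEth_release] * y[PEth_Bound];
  ydot[timeElapsed] = 1.0;

  ydot[cumIngested] = r_EtOH_in;
  ydot[cumElimStoADH] = r_sto_ADH;
  ydot[cumElimADH] = r_elim_ADH * V_liver;
  ydot[cumElimCYP2E1] = r_elim_CYP * V_liver;
  ydot[cumEtGsynth] = r_EtG * V_liver;
  ydot[cumEtSsynth] = r_EtS * V_liver;
  ydot[cumTissueNet] = r_tissue_per * V_bp;
  ydot[cumVoidedEtOH] = 0.0;
}

static const R_CMethodDef cMethods[] = {
  {"alcotwin_initmod", (DL_FUNC) &alcotwin_initmod, 1},
  {"alcotwin_derivs", (DL_FUNC) &alcotwin_derivs, 6},
  {NULL, NULL, 0}
};

void R_init_alcotwin(DllInfo *info) {
  R_registerRoutines(info, cMethods, NULL, NULL, NULL);
}
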