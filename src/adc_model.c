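/* Coupled plasma / tumor-extracellular / single-cell / tumor-volume ODE
 * right-hand side for the T-vc-MMAE systems PK-PD model, in the form
 * expected by deSolve's compiled-code interface.
 *
 * Units used throughout: time in days, ADC amounts in nmol (per animal),
 * drug concentrations in nM, per-cell species in molecules/cell, tumor
 * volumes in mm^3.  All rate parameters must already be per-day and all
 * volumes per-animal (litres); the R side performs those conversions once
 * at parameter load.
 */
#include <R.h>
#include <math.h>

static double parms[36];

#define CLA   parms[0]   /* ADC central clearance, L/day (per animal)      */
#define CLDA  parms[1]   /* ADC distributional clearance, L/day            */
#define V1A   parms[2]   /* ADC central volume, L                          */
#define V2A   parms[3]   /* ADC peripheral volume, L                       */
#define CLD_  parms[4]   /* free drug central clearance, L/day             */
#define CLDD  parms[5]   /* free drug distributional clearance, L/day      */
#define V1D   parms[6]   /* free drug central volume, L                    */
#define V2D   parms[7]   /* free drug peripheral volume, L                 */
#define KDEC  parms[8]   /* non-specific deconjugation rate, 1/day         */
#define KVA   parms[9]   /* ADC vascular exchange 2*P*Rcap/Rkrogh^2, 1/day */
#define SDA   parms[10]  /* ADC surface exchange numerator 6*D, cm^2/day   */
#define KVD   parms[11]  /* drug vascular exchange, 1/day                  */
#define SDD   parms[12]  /* drug surface exchange numerator 6*D, cm^2/day  */
#define EPSA  parms[13]  /* ADC void volume fraction                       */
#define EPSD  parms[14]  /* drug void volume fraction                      */
#define KONA  parms[15]  /* ADC-antigen association, 1/nM/day              */
#define KOFFA parms[16]  /* ADC-antigen dissociation, 1/day                */
#define KINT  parms[17]  /* internalization, 1/day                         */
#define KDEG  parms[18]  /* lysosomal degradation, 1/day                   */
#define KONT  parms[19]  /* drug-tubulin association, 1/nM/day             */
#define KOFFT parms[20]  /* drug-tubulin dissociation, 1/day               */
#define TUBM  parms[21]  /* total tubulin, molecules/cell                  */
#define KIN   parms[22]  /* drug influx, 1/day                             */
#define KOUT  parms[23]  /* drug efflux, 1/day                             */
#define AG    parms[24]  /* antigen, receptors/cell                        */
#define VCELL parms[25]  /* single-cell volume, L                          */
#define SF    parms[26]  /* nmol per molecule, 1e9/Avogadro                */
#define CPM   parms[27]  /* cells per mm^3 tumor                           */
#define KG    parms[28]  /* tumor growth rate 0.693/DT, 1/day              */
#define KMAX  parms[29]  /* maximum kill rate, 1/day                       */
#define KC50  parms[30]  /* occupancy at half-maximal kill, percent        */
#define GAM   parms[31]  /* Hill coefficient                               */
#define TAU   parms[32]  /* transit time, day                              */
#define KILL_ON    parms[33]
#define RELEASE_ON parms[34]
#define TUMOR_ON   parms[35]

static double fm(double x) { return x > 0.0 ? x : 0.0; }

void adc_initmod(void (*odeparms)(int *, double *))
{
    int n = 36;
    odeparms(&n, parms);
}

void adc_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double X1 = y[0], X2 = y[1], C1 = y[2], C2 = y[3], DAR = y[4];
    double ADCf = y[5], DRGf = y[6];
    double ADCb = y[7], LYSO = y[8], DFC = y[9], DBC = y[10];
    double TV1 = y[11], TV2 = y[12], TV3 = y[13], TV4 = y[14];
    double dar = fm(DAR);

    /* plasma two-compartment disposition of conjugate and free payload;
     * both catabolic clearance and deconjugation form free payload,
     * scaled by the current average DAR */
    double dX1 = -(CLA + CLDA) / V1A * X1 + CLDA / V2A * X2 - KDEC * X1;
    double dX2 = CLDA / V1A * X1 - CLDA / V2A * X2;
    double dC1 = -(CLD_ + CLDD) / V1D * C1 + CLDD / V1D * C2
                 + KDEC * X1 * dar / V1D
                 + CLA * dar * X1 / (V1A * V1D);
    double dC2 = CLDD / V2D * (C1 - C2);
    double dDAR = -KDEC * DAR;

    double dADCf = 0.0, dDRGf = 0.0;
    double dADCb = 0.0, dLYSO = 0.0, dDFC = 0.0, dDBC = 0.0;
    double dTV1 = 0.0, dTV2 = 0.0, dTV3 = 0.0, dTV4 = 0.0;

    if (TUMOR_ON > 0.5) {
        double TVmm3 = fm(TV1) + fm(TV2) + fm(TV3) + fm(TV4);
        double TV_L = TVmm3 * 1e-6;
        double R = cbrt(3.0 * TV_L * 1000.0 / (4.0 * M_PI)); /* cm */
        double kexA = KVA + SDA / (R * R);
        double kexD = KVD + SDD / (R * R);
        double NC = TVmm3 * CPM;

        /* Krogh-cylinder exchange with plasma (amount fluxes, nmol/day) */
        double fluxA = (X1 / V1A - fm(ADCf) / EPSA) * TV_L * kexA;
        double fluxD = (C1 - fm(DRGf) / (TV_L * EPSD)) * TV_L * kexD;
        dX1 -= fluxA;
        dC1 -= fluxD / V1D;

        /* single-cell disposition (molecules/cell/day) */
        double bind = KONA * fm(ADCf) / EPSA * (AG - fm(ADCb));
        double tubb = KONT * (SF / VCELL) * fm(DFC) * (TUBM - fm(DBC));
        double influx = KIN * (VCELL / (TV_L * EPSD)) * fm(DRGf);

        dADCb = bind - KOFFA * ADCb - (KDEC + KINT) * ADCb - KG * ADCb;
        dLYSO = KINT * fm(ADCb) - KDEG * LYSO - KG * LYSO;
        dDFC  = KDEG * fm(LYSO) * dar - KOUT * DFC - tubb + KOFFT * fm(DBC)
                + influx / SF - KG * DFC;
        dDBC  = tubb - KOFFT * DBC - KG * DBC;

        /* tumor extracellular balances: conjugate as nM per total tumor
         * volume, free payload as amount in nmol */
        dADCf = fluxA / TV_L
                + (-bind + KOFFA * fm(ADCb)) * NC * SF / TV_L
                - KDEC * fm(ADCf);
        dDRGf = fluxD
                + KDEC * fm(ADCf) * dar * TV_L
                + (KDEC * fm(ADCb) * dar + KOUT * fm(DFC)) * NC * SF
                - influx * NC;

        /* occupancy-driven kill shuttles growing volume through three
         * non-growing transit compartments */
        double kill = 0.0;
        if (KILL_ON > 0.5 && DBC > 0.0) {
            double occ = 100.0 * fm(DBC) / TUBM;
            double po = pow(occ, GAM);
            kill = KMAX * po / (pow(KC50, GAM) + po);
        }
        dTV1 = (KG - kill) * TV1;
        dTV2 = kill * fm(TV1) - TV2 / TAU;
        dTV3 = (fm(TV2) - TV3) / TAU;
        dTV4 = (fm(TV3) - TV4) / TAU;

        /* dying cells in the last transit compartment release their
         * intracellular content back into the extracellular space */
        if (RELEASE_ON > 0.5) {
            double rel = fm(TV4) * CPM * SF / TAU; /* nmol/day per molecule */
            dADCf += rel * (fm(ADCb) + fm(LYSO)) / TV_L;
            dDRGf += rel * (fm(DFC) + fm(DBC));
        }
    }

    ydot[0] = dX1;  ydot[1] = dX2;  ydot[2] = dC1;  ydot[3] = dC2;
    ydot[4] = dDAR; ydot[5] = dADCf; ydot[6] = dDRGf;
    ydot[7] = dADCb; ydot[8] = dLYSO; ydot[9] = dDFC; ydot[10] = dDBC;
    ydot[11] = dTV1; ydot[12] = dTV2; ydot[13] = dTV3; ydot[14] = dTV4;
}
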