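# Frozen independent reference values for the 2D DWT, computed once with
# PyWavelets (pywt.dwt2, mode = "periodization") on the deterministic
# fixture X[i, j] = ((7 i + 13 j) mod 31) + 0.5 sin(i + 2 j), i, j = 1..32.
# Convention alignment (verified against the periodic filter-bank
# definition): with filter length L and s = (L - 2) / 2, this package's
# analysis step equals PyWavelets' after reflecting-and-shifting both the
# input and each output axis by k -> (s - k) mod n. The arrays below are
# already aligned, so tests compare them to dwt2d() output directly.

dwtReferenceFixture <- function() {
  i <- matrix(1:32, 32, 32)
  j <- t(i)
  ((7 * i + 13 * j) %% 31) + 0.5 * sin(i + 2 * j)
}

dwtReference_haar_LL <- matrix(c(40.62015477977609, 29.350550524257415, 26.841214651511848, 24.78160551666935, 20.50826002210867, 48.627666555737136, 15.801630747832728, 42.70514124468386, 8.443778328673362, 37.75779853319925, 33.925510746664784, 30.304198401065186, 28.65360052185756, 25.15181401986166, 52.220045629924584, 19.49733706765436, 16.75066301233048, 38.44476195809625, 34.96436635360627, 31.58489570034654, 29.381122328669548, 26.097898596826845, 38.037397288586675, 20.28712271303874, 32.72363229394953, 29.026749543607508, 26.67025106669493, 23.831551570744757, 35.55380065866975, 33.039817317983264, 30.413059639493216, 26.616395757455944, 37.8101799728137, 27.584895700346536, 25.381122328669548, 22.097898596826845, 34.03739728858667, 31.78712271303874, 28.72363229394953, 25.026749543607508, 38.17025106669493, 35.33155157074476, 31.55380065866975, 29.039817317983264, 26.413059639493213, 38.11639575745595, 19.906211744548344, 32.96166361416703, 28.497486287434505, 33.597898596826845, 30.037397288586668, 27.78712271303874, 40.223632293949535, 21.026749543607508, 34.17025106669493, 31.331551570744757, 27.553800658669743, 25.039817317983264, 22.413059639493213, 34.11639575745595, 31.406211744548344, 28.96166361416703, 25.209548550282605, 37.78007728977383, 17.539462550688953, 23.78712271303874, 36.22363229394953, 32.52674954360751, 30.17025106669493, 27.331551570744754, 23.553800658669747, 36.539817317983264, 33.91305963949321, 30.11639575745594, 27.406211744548344, 40.46166361416703, 21.209548550282605, 33.78007728977383, 31.473491730008394, 27.82583853907773, 39.104568444387446, 28.52674954360751, 26.17025106669493, 38.83155157074476, 19.553800658669747, 32.539817317983264, 29.913059639493213, 26.116395757455944, 23.406211744548344, 36.46166361416703, 32.709548550282605, 29.78007728977383, 27.473491730008398, 23.82583853907773, 36.17146175201408, 33.94760176609044, 29.323836456076094, 34.83155157074476, 31.05380065866975, 28.539817317983264, 25.913059639493213, 37.61639575745595, 34.906211744548344, 32.46166361416704, 28.70954855028261, 25.780077289773825, 38.97349173000839, 19.825838539077726, 32.17146175201408, 29.947601766090443, 26.456002130003025, 23.089017382737673, 18.47208428817813, 40.039817317983264, 21.913059639493213, 33.61639575745595, 30.906211744548344, 28.46166361416703, 24.709548550282605, 21.78007728977383, 34.973491730008405, 31.32583853907773, 28.171461752014082, 25.947601766090443, 37.95600213000303, 34.58901738273767, 32.38605610209615, 29.089670566028268, 40.36630101869599, 29.616395757455944, 26.906211744548344, 24.46166361416703, 36.209548550282605, 33.28007728977383, 30.973491730008398, 27.32583853907773, 39.67146175201408, 21.947601766090443, 33.95600213000302, 30.589017382737673, 28.386056102096152, 25.08967056602827, 21.539311653135748, 34.79375743033512, 30.049055063448925, 20.461663614167033, 32.209548550282605, 29.28007728977383, 26.973491730008394, 23.32583853907773, 35.67146175201408, 33.44760176609044, 29.95600213000303, 26.589017382737673, 24.38605610209615, 36.58967056602827, 33.03931165313574, 30.793757430335127, 27.716195896171904, 39.52630409313206, 19.569569922715118, 25.28007728977383, 38.4734917300084, 34.82583853907773, 31.671461752014082, 29.44760176609044, 25.95600213000302, 38.08901738273767, 20.38605610209615, 32.58967056602827, 29.039311653135748, 26.79375743033512, 23.716195896171904, 35.52630409313206, 33.17805821008495, 30.32549918517175, 41.51364068504127, 30.82583853907773, 27.671461752014075, 25.447601766090443, 21.95600213000302, 34.08901738273767, 31.886056102096155, 28.589670566028268, 25.039311653135748, 38.29375743033513, 35.21619589617191, 31.52630409313206, 29.178058210084945, 26.32549918517175, 38.051030877499265, 20.04817497490031, 30.75895416289841, 36.94760176609044, 33.45600213000303, 30.089017382737676, 27.88605610209615, 40.08967056602827, 21.039311653135744, 34.29375743033512, 31.216195896171904, 27.526304093132058, 25.17805821008495, 22.32549918517175, 34.051030877499265, 31.548174974900313, 28.90887339568974, 25.11152228477055, 20.801475462473114, 26.089017382737673, 23.88605610209615, 36.08967056602827, 32.53931165313575, 30.293757430335127, 27.216195896171904, 23.52630409313206, 36.678058210084956, 33.82549918517175, 30.05103087749927, 27.54817497490031, 40.40887339568974, 21.11152228477055, 33.91445414883386, 31.4596769859145, 42.5005744321803, 32.08967056602827, 28.53931165313574, 26.293757430335123, 38.716195896171904, 19.52630409313206, 32.67805821008495, 29.825499185171754, 26.051030877499265, 23.54817497490031, 36.40887339568974, 32.61152228477055, 29.914454148833862, 27.4596769859145, 23.702959604122462, 36.28754785622782, 31.54412996880274, 22.293757430335127, 34.71619589617191, 31.02630409313206, 28.67805821008495, 25.82549918517175, 37.551030877499265, 35.04817497490031, 32.40887339568974, 28.61152228477055, 25.914454148833862, 38.9596769859145, 19.702959604122462, 32.28754785622781, 29.973862970974466, 26.318058991116494), 16, 16)

dwtReference_haar_LH <- matrix(c(-0.28505343268613714, -0.20841390924294423, 0.3475708987480868, -0.08086715073678086, -0.2802656808286983, 0.31413050367597606, 0.018816850093267945, -0.32979164895616364, 0.25566665277227685, 0.11700191143260241, -0.3530466033975692, 0.1768365428826204, 0.20586666758449468, -0.34817806781420124, 0.08391973536745923, 0.2783322030201205, 13.726014576383609, 13.25597640783632, -18.736372012326306, 13.356901359066573, -17.560674730743557, 12.277450998900848, -2.337952307141027, 13.587677731593104, -3.151168150682315, -2.5457145996597053, -1.8107838772528773, -3.0279156186973015, 12.750164706622295, -17.264148047308783, 12.637390368818732, -18.434054250856004, -18.768435850046863, 13.356901359066569, -17.560674730743557, 12.277450998900848, -2.3379523071410233, -1.9123222684068963, -3.15116815068232, -2.5457145996597053, 13.689216122747126, -18.527915618697307, 12.750164706622295, -17.26414804730878, 12.637390368818728, -2.934054250855997, 13.723870237948399, -2.668418368329709, -17.721448193531536, -3.2225490010991518, -2.337952307141025, -1.9123222684068946, 12.348831849317689, -2.5457145996597053, 13.689216122747132, -18.5279156186973, 12.750164706622293, -17.26414804730878, 12.637390368818728, -2.934054250855997, -1.7761297620516014, -2.668418368329709, -3.0836966955547194, 13.654225435045943, -17.595711372709438, -1.9123222684068981, 12.348831849317683, -18.045714599659707, 13.689216122747132, -18.527915618697303, 12.750164706622297, -1.764148047308776, -2.86260963118127, -2.934054250855999, -1.7761297620515997, 12.83158163167029, -3.083696695554721, 13.654225435045943, -17.96081099481138, 12.313157803880708, 12.192926829099171, -18.045714599659707, 13.689216122747126, -3.0279156186972997, 12.750164706622295, -1.764148047308776, -2.8626096311812717, -2.934054250855997, -1.7761297620516032, 12.831581631670295, -18.58369669555472, 13.654225435045944, -17.960810994811382, 12.313157803880708, -1.9675345909443607, -2.2563253949792834, 13.650787832168433, -3.027915618697305, -2.749835293377709, -1.7641480473087796, -2.8626096311812734, 12.565945749144003, -17.27612976205161, 12.831581631670293, -18.583696695554725, 13.65422543504594, -2.4608109948113785, 12.31315780388071, -1.9675345909443553, -2.2563253949792834, -3.23527424110814, -2.131710506157212, 12.956306540835724, 13.735851952691222, -2.8626096311812734, 12.565945749144003, -17.276129762051603, 12.831581631670295, -18.58369669555472, 13.654225435045944, -2.4608109948113714, -3.186842196119292, -1.9675345909443536, -2.25632539497928, 12.264725758891865, -17.63171050615722, 13.428749225515693, -18.72513476158357, -18.59366793045605, 12.565945749144003, -17.276129762051603, 12.831581631670295, -3.0836966955547176, -1.8457745649540556, -2.460810994811375, -3.186842196119292, 13.532465409055648, -2.25632539497928, 12.264725758891856, -17.631710506157212, 13.428749225515691, -18.725134761583572, 13.17477584869105, -1.920330071491673, -17.180212029527937, 12.831581631670295, -3.0836966955547194, -1.8457745649540573, -2.4608109948113714, -3.186842196119292, 13.532465409055646, -17.75632539497928, 12.264725758891863, -17.63171050615722, 13.42874922551569, -3.2251347615835684, -2.325224151308948, -1.9203300714916711, -3.1572314626715468, 12.967339659631705, -18.478030424263544, -1.8457745649540591, 13.039189005188627, -18.6868421961193, 13.532465409055648, -17.75632539497928, 12.264725758891862, -2.131710506157212, 13.428749225515693, -3.2251347615835737, -2.3252241513089498, -1.9203300714916711, -3.157231462671545, 12.967339659631705, -17.315585542678814, 12.463026517765618, 12.805135104325116, -18.686842196119294, 13.532465409055646, -17.756325394979285, 12.264725758891862, -2.131710506157214, -2.0712507744843123, -3.22513476158357, -2.3252241513089515, 13.57966992850833, -18.65723146267155, 12.967339659631705, -17.315585542678814, 12.463026517765618, -2.7374948254381053, 13.73463892283915, 13.732774816239829, -2.2563253949792816, -3.23527424110814, -2.1317105061572086, -2.0712507744843105, 12.274865238416432, -2.3252241513089515, 13.579669928508325, -18.657231462671547, 12.967339659631701, -17.315585542678818, 12.46302651776562, -2.7374948254381035, -1.765361077160854, -2.873940502049722, -2.923410608869464, 12.23691772734555, -2.1317105061572104, -2.0712507744843105, 12.27486523841643, -17.82522415130896, 13.57966992850833, -18.657231462671547, 12.967339659631705, -1.8155855426788143, -3.0369734822343855, -2.7374948254381017, -1.765361077160854, 12.62605949795028, -2.9234106088694656, 13.726342472932773, -18.18111963585214, -17.735207096810445, 12.27486523841643, -17.82522415130895, 13.579669928508327, -3.1572314626715468, 12.967339659631705, -1.8155855426788126, -3.0369734822343837, -2.7374948254381017, -1.7653610771608506, 12.62605949795028, -18.42341060886946, 13.726342472932776, -18.18111963585214, 12.424402254060107, -1.8398140019547533, -17.58307811138516, 13.579669928508332, -3.1572314626715503, -2.532660340368297, -1.8155855426788108, -3.0369734822343837, 12.762505174561895, -17.265361077160854, 12.626059497950276, -18.423410608869467, 13.726342472932778, -2.6811196358521414, 12.424402254060107, -1.8398140019547498, -2.4738708832985967, -3.1819330965593657), 16, 16)

dwtReference_haar_HL <- matrix(c(-0.13618043600109891, -24.257772651076642, 7.429886240955955, -24.10001894742129, 6.653358896172332, 7.388526144971475, 7.0232732515361995, 6.592103675022615, 7.316216279020889, 7.1447115166188855, -24.43665875872666, 7.218716805570522, -23.74537785474908, 6.569362793907443, 7.103794476778916, 7.34424971976734, 0.09836814969734584, 7.0897905838840245, 6.741697785739259, 7.125192714791439, 7.154105109822331, 6.746546577311939, -8.443157429694965, 7.206143711060767, -8.728414676769082, -8.516035620743981, -8.258238977541563, -8.685180548648985, 6.9123635765622415, 7.2581197894088465, 6.872804955812351, 6.8477438411174845, -0.10411583346816389, 7.125192714791437, 7.15410510982233, 6.746546577311939, -8.443157429694967, -8.293856288939237, -8.728414676769084, -8.516035620743981, 7.241761022458439, 6.814819451351018, 6.912363576562241, 7.258119789408846, 6.8728049558123505, -8.652256158882519, 7.253916881915206, -8.55907725542734, 0.0377411510573844, -8.753453422688063, -8.443157429694967, -8.293856288939235, 6.7715853232309176, -8.516035620743978, 7.241761022458441, 6.814819451351019, 6.912363576562239, 7.258119789408846, 6.8728049558123505, -8.652256158882519, -8.246083118084794, -8.55907725542734, -8.704747255999255, 7.229487101178934, 0.05477730820274782, -8.293856288939235, 6.771585323230916, 6.983964379256021, 7.24176102245844, 6.814819451351017, 6.912363576562241, -8.241880210591159, -8.627195044187651, -8.652256158882519, -8.246083118084794, 6.940922744572664, -8.704747255999258, 7.229487101178936, 7.01374659363128, 6.7590716959151536, -0.10935082720699685, 6.983964379256024, 7.241761022458441, -8.685180548648987, 6.912363576562242, -8.241880210591157, -8.627195044187651, -8.652256158882514, -8.246083118084798, 6.94092274457266, 6.795252744000745, 7.229487101178934, 7.01374659363128, 6.7590716959151536, -8.313223490472126, -8.414524603077837, 0.0881756330772767, -8.685180548648987, -8.587636423437761, -8.241880210591159, -8.627195044187651, 6.847743841117487, 7.253916881915206, 6.940922744572661, 6.795252744000745, 7.229487101178934, -8.486253406368721, 6.759071695915155, -8.313223490472128, -8.414524603077838, -8.757917141591417, -8.370812591793067, -0.005920052946149557, 7.258119789408843, -8.627195044187651, 6.847743841117488, 7.253916881915206, 6.940922744572662, 6.795252744000745, 7.229487101178935, -8.486253406368721, -8.740928304084848, -8.313223490472126, -8.414524603077837, 6.742082858408587, 7.129187408206934, 7.150395279097337, 6.7456395525371065, -0.08043642339042602, 6.847743841117486, 7.253916881915205, 6.940922744572662, -8.704747255999258, -8.270512898821067, -8.486253406368721, -8.740928304084848, 7.186776509527876, -8.414524603077837, 6.742082858408587, 7.129187408206932, 7.150395279097334, 6.7456395525371065, 7.061307312011464, -8.296665240438664, 0.11107356301462343, 6.940922744572662, -8.704747255999258, -8.270512898821064, -8.486253406368721, -8.740928304084848, 7.186776509527878, 7.085475396922165, 6.742082858408586, 7.129187408206933, 7.150395279097335, -8.754360447462895, -8.438692687988539, -8.296665240438667, -8.730541545914512, 6.9885435104886895, -0.06476862843177425, -8.270512898821064, 7.0137465936312795, 6.759071695915152, 7.186776509527876, 7.085475396922163, 6.742082858408587, -8.370812591793069, 7.150395279097334, -8.754360447462895, -8.438692687988535, -8.296665240438667, -8.730541545914514, 6.988543510488688, 7.240076709650648, 6.811642163011786, -0.026402361401595853, 6.759071695915152, 7.186776509527876, 7.085475396922163, 6.742082858408586, -8.370812591793069, -8.349604720902668, -8.754360447462894, -8.438692687988539, 7.203334759561338, 6.769458454085491, 6.988543510488688, 7.240076709650648, 6.811642163011785, -8.58330767364763, 7.257694286685343, 0.09928409864354687, -8.414524603077837, -8.757917141591417, -8.37081259179307, -8.349604720902668, 6.745639552537108, -8.438692687988539, 7.203334759561338, 6.769458454085491, 6.988543510488688, 7.2400767096506495, 6.8116421630117845, -8.583307673647635, -8.242305713314659, -8.631169650753126, -8.64852261626153, -0.10339047406150517, -8.370812591793069, -8.349604720902668, 6.7456395525371065, 7.061307312011465, 7.203334759561336, 6.769458454085493, 6.988543510488688, -8.259923290349356, -8.688357836988214, -8.583307673647631, -8.242305713314659, 6.868830349246877, -8.648522616261532, 7.254784084579006, 6.936467434661307, 0.035876949013186915, 6.745639552537106, 7.061307312011465, 7.203334759561339, -8.730541545914509, 6.988543510488688, -8.259923290349356, -8.688357836988214, -8.583307673647631, -8.242305713314659, 6.868830349246877, 6.8514773837384695, 7.254784084579008, 6.936467434661307, 6.798093667587839, -8.268422071636994, 0.05648899634446861, 7.203334759561338, -8.730541545914512, -8.511456489511312, -8.259923290349352, -8.688357836988214, 6.9166923263523685, 7.257694286685345, 6.868830349246878, 6.8514773837384695, 7.254784084579008, -8.563532565338697, 6.798093667587841, -8.268422071636994, -8.49083451219265, -8.739206305875886), 16, 16)

dwtReference_haar_HH <- matrix(c(-0.057800903028981096, 0.1567117613990341, 0.03831480750290117, -0.18860093326952665, 0.11865655599700364, 0.08984383244206695, -0.1934330093050769, 0.07114923737013656, 0.134215949196427, -0.182856322714668, 0.017974211284279562, 0.16789650038390125, -0.1577134062884724, -0.03663263016785878, 0.18820251260598564, -0.12000713033455002, 0.0819408603073572, -0.3784104645748356, 0.030317666430075718, 0.35317726262210325, -0.3242648675912081, -0.08329366491918533, -15.106410342087718, -0.2442885171565492, -15.6902698706733, 15.902648926698408, -15.64485228349599, 15.217910712388568, 0.37963341282265706, -0.033877199976055206, -0.35143763362043945, 0.32637651892557473, 0.06238150415062946, 0.35317726262210236, -0.32426486759120676, -0.08329366491918622, -15.10641034208772, 15.25571148284345, -15.690269870673298, 15.902648926698408, -0.14485228349598822, -0.28208928761143603, 0.3796334128226584, -0.03387719997605565, -0.351437633620439, -15.17362348107443, 0.07979652187214681, -15.892790659214693, -0.16349140480323093, 15.416706335080816, -15.10641034208772, 15.255711482843452, -0.19026987067329948, 15.902648926698404, -0.1448522834959869, -0.2820892876114356, 0.3796334128226566, -0.03387719997605565, -0.351437633620439, -15.17362348107443, 15.579796521872147, -15.892790659214693, 15.747120658642775, 0.18711369853541937, 0.15134872348069275, 15.255711482843449, -0.1902698706732977, 0.40264892669840524, -0.144852283495986, -0.28208928761143426, 0.37963341282265795, -15.533877199976057, 15.148562366379565, -15.17362348107443, 15.579796521872147, -0.3927906592146915, 15.747120658642775, 0.18711369853541804, -0.4028542060830711, 0.14817930836694604, -0.03436485045478335, 0.40264892669840346, -0.1448522834959869, -15.782089287611438, 0.3796334128226593, -15.53387719997606, 15.148562366379565, -15.173623481074427, 15.57979652187215, -0.39279065921469103, 0.247120658642773, 0.1871136985354167, -0.4028542060830733, 0.14817930836694604, -15.220474494754225, 15.119173382148514, -0.10642399291729239, -15.782089287611438, 15.879633412822663, -15.533877199976057, 15.148562366379561, 0.3263765189255743, 0.07979652187214681, -0.3927906592146915, 0.247120658642773, 0.1871136985354167, -15.902854206083074, 0.14817930836694648, -15.220474494754226, 15.119173382148512, -15.46256592066209, 15.849670470460437, 0.17349157860922595, -0.033877199976055206, 15.148562366379565, 0.3263765189255734, 0.07979652187214681, -0.3927906592146897, 0.24712065864277344, 0.18711369853541626, -15.902854206083074, 15.648179308366947, -15.220474494754225, 15.119173382148514, 0.037434079337911985, 0.34967047046043565, -0.32846259957003276, -0.07629312699019453, -0.12037933434566676, 0.32637651892557296, 0.07979652187214636, -0.3927906592146897, -15.252879341357229, 15.68711369853542, -15.902854206083074, 15.648179308366947, 0.27952550524577635, 15.119173382148514, 0.03743407933791154, 0.34967047046043653, -0.32846259957003276, -0.07629312699019364, 0.3919608864645516, -15.749933438914677, -0.01612121065152381, -0.3927906592146897, -15.252879341357229, 15.687113698535416, -15.902854206083074, 15.648179308366947, 0.2795255052457799, -0.3808266178514894, 0.037434079337909765, 0.3496704704604343, -0.32846259957003365, -15.576293126990196, 15.891960886464553, -15.749933438914681, 15.316057133438836, 0.4030279229643665, 0.14145438735159868, 15.687113698535416, -0.40285420608307376, 0.1481793083669456, 0.279525505245779, -0.3808266178514885, 0.0374340793379111, -15.150329529539569, -0.32846259957003454, -15.576293126990196, 15.891960886464553, -15.749933438914681, 15.316057133438834, 0.4030279229643652, -0.1514947238024047, -0.2769398228364568, -0.1688003052195645, 0.1481793083669456, 0.27952550524577857, -0.3808266178514885, 0.037434079337909765, -15.150329529539569, 15.171537400429969, -15.576293126990194, 15.891960886464553, -0.2499334389146779, -0.1839428665611682, 0.40302792296436474, -0.1514947238024038, -0.2769398228364581, -15.118010013822962, -0.0409880258440678, 0.07921609806159638, -15.88082661785149, 15.537434079337917, -15.150329529539567, 15.171537400429969, -0.0762931269901932, 15.891960886464553, -0.2499334389146779, -0.18394286656117087, 0.4030279229643652, -0.15149472380240603, -0.2769398228364577, -15.118010013822964, 15.459011974155933, -15.8478759115944, 15.830522946085992, 0.06524211088422388, -15.150329529539569, 15.171537400429969, -0.07629312699019408, 0.3919608864645503, -0.24993343891467967, -0.18394286656116998, 0.40302792296436474, -15.651494723802408, 15.223060177163543, -15.11801001382296, 15.459011974155933, -0.34787591159439746, 15.830522946085994, 0.07278375475454446, -0.3911004046722457, -0.16450627724389597, -0.07629312699019586, 0.3919608864645503, -0.24993343891467656, -15.683942866561168, 0.40302792296436474, -15.651494723802408, 15.223060177163543, -15.11801001382296, 15.459011974155933, -0.3478759115944001, 0.3305229460859924, 0.07278375475454579, -0.3911004046722457, 0.25272663759877867, -15.319242376823613, 0.149814846540762, -0.24993343891467834, -15.683942866561171, 15.903027922964364, -15.651494723802404, 15.223060177163543, 0.38198998617703994, -0.04098802584406647, -0.34787591159440057, 0.33052294608599064, 0.07278375475454579, -15.891100404672247, 0.25272663759878, -15.319242376823613, 15.096829936267953, -15.345201729951189), 16, 16)

dwtReference_db2_LL <- matrix(c(35.20876518830083, 38.09526414071768, 20.716049565810607, 30.07703498041802, 15.74780195567029, 42.45241531492657, 22.907684443052354, 36.922957870758694, 14.664863049041708, 31.19066017851605, 44.002422825027274, 24.509260052513003, 36.98161994079789, 19.811023647339876, 46.41897322118839, 22.997296394416082, 17.597108283015192, 31.88601108976991, 38.45837914010801, 29.007749273853662, 32.166026143724196, 25.284651786673848, 38.92626469801727, 16.84000552445982, 33.770575450104246, 32.336982608580485, 26.189838023231253, 26.719747410137572, 27.467344973332505, 35.79814902554813, 29.318737885129103, 30.741575292779164, 42.60946695224635, 27.61834236333141, 25.8317059643069, 23.269393078678902, 32.1024431948769, 36.47084159830346, 29.27330951753212, 29.530805090434196, 29.82393375932215, 36.66198789448018, 30.33061897273322, 29.909322567730054, 28.137872348733726, 36.430437982299665, 18.536025902204067, 30.690303271816955, 29.678950773310397, 39.65698134690576, 24.746594755212204, 32.47084159830346, 32.50415795719682, 25.530805090434193, 26.34308531965745, 32.66198789448019, 29.68646741239792, 25.52927724873595, 23.23867546940432, 32.430437982299665, 36.228571221198166, 29.146954832152257, 29.878239672746965, 29.66112084002894, 20.657541087408536, 25.78806421673851, 29.023309517532116, 34.055001969763595, 31.511433759322152, 30.21944257548608, 25.68646741239792, 34.05347412806535, 38.99372078839842, 25.074589542634964, 32.228571221198166, 32.37780327181696, 25.87823967274697, 26.180272400364238, 32.45006147479316, 30.02566534995816, 27.90729926789351, 29.675198705381934, 27.511433759322152, 36.80613945481548, 18.849770533068522, 30.053474128065353, 34.99372078839842, 26.887089542634968, 23.973525902204067, 28.896954832152257, 34.40243655207637, 31.34862084002894, 30.00751615579906, 26.025665349958164, 33.98308825039435, 38.71310457149894, 27.061735697493674, 31.505659948461332, 36.54231585206263, 28.510125688400656, 30.094523909069025, 30.117937982299665, 35.853571221198166, 30.709454832152257, 30.402436552076367, 27.34862084002894, 36.59421303512846, 19.188968470628765, 29.983088250394353, 34.713104571498945, 27.191030522199053, 24.00117396481828, 22.720541600951364, 33.838993959930455, 26.09452390906902, 26.637089542634968, 31.853571221198173, 30.065303271816955, 26.02239123308227, 22.449423960699537, 32.59421303512846, 36.881513789622865, 28.439739810729655, 29.813907692169543, 30.421878961863754, 35.88121928381238, 30.382502545001046, 30.646908809461813, 44.834572821883846, 29.994180201279285, 29.411025902204067, 26.06530327181696, 34.54658811241166, 38.20446927969364, 25.23836459546376, 32.881513789622865, 31.670588250394353, 25.813907692169543, 26.941030522199057, 31.881219283812374, 29.738350984665743, 26.266863490467717, 22.57290353478176, 32.246969509478006, 31.192039633885067, 19.876159959249982, 30.54658811241167, 34.20446927969364, 27.05086459546376, 24.62646847062877, 28.189739810729655, 34.338104571498945, 32.109378961863754, 29.43867396481828, 25.738350984665743, 34.791060369797115, 38.327948853775865, 24.891121069813302, 33.04704280496248, 31.880063023864132, 23.068967938196632, 30.88347699676658, 30.281713035128462, 36.50651378962286, 30.002239810729648, 30.338104571498942, 28.109378961863754, 36.02537084414767, 18.901654105336345, 30.791060369797115, 34.327948853775865, 26.703621069813302, 24.791997485968377, 28.39921458419943, 33.99823102752758, 32.182778788693476, 33.21220577404425, 32.103938989177394, 29.35808825039435, 25.958059252504842, 23.210182082534352, 32.02537084414767, 36.59419942433045, 29.247711930132418, 29.428751974446463, 29.934469509478, 36.67204280496247, 30.21171458419943, 29.998231027527577, 28.182778788693476, 36.30415417664245, 18.596224674707088, 28.197753026121994, 33.20560890507765, 38.96522740152845, 24.669522404482976, 32.59419942433045, 32.47856036979712, 25.42875197444646, 26.453621069813302, 32.67204280496247, 29.567563023864132, 25.61818570853348, 23.283581909364077, 32.30415417664244, 36.28876999370119, 29.223135580327167, 29.754636145526376, 25.22227684647381, 28.571658137352728, 24.339154105336352, 28.997711930132418, 33.95294885377586, 31.621969509478, 30.229497485968373, 25.56756302386413, 34.14238258786288, 39.03862722835818, 24.948305736977748, 32.28876999370119, 32.45398401999187, 25.754636145526383, 26.20696608586716, 32.5514480164581, 46.52349184772387, 28.986082295164483, 29.952948853775855, 27.621969509478, 36.816194365297775, 18.73086614453473, 30.142382587862883, 35.03862722835817, 26.76080573697775, 24.033724674707088, 28.97313558032717, 34.27883302485577, 31.37531452553186, 30.108902697464003, 25.914588287290606, 33.97415044521352, 29.74112813736134, 21.458037506349392, 32.816194365297775, 36.42341146352883, 28.599034148198182, 30.139430349028775, 29.991654176642445, 35.91376999370119, 30.78563558032717, 30.27883302485578, 27.375314525531856, 36.6955995767934, 19.07789140796121, 29.974150445213517, 34.83162051286986, 27.101328259216064), 16, 16)

dwtReference_db2_LH <- matrix(c(-22.157078125838034, 7.0453865739058, 6.418153183869758, -10.16533081551884, 9.514961524906493, -15.04906267549675, 18.082277215196022, -15.628396066688838, 15.528351487761242, -17.134846314861026, 6.811889346251652, 7.106395585057475, 2.0633730020675136, 7.135156129450783, -14.385441631540445, 5.448058135105283, 6.028097693143927, 0.8715700230267851, -4.850513725997056, 1.021241363820593, -5.450794491029077, 5.982291139861992, -5.473140530015096, 6.103943957155389, -6.019155681461772, 1.1433876561599774, 3.8853374384649464, -0.9911971688414176, 2.7070086494879755, -5.161859498228619, 5.613499768757144, -2.0992843582885237, 5.333166117404781, 15.445753157919452, -14.162596001747719, 13.389446481504741, -16.01178585124048, 7.525243534094905, 5.548416351964708, 5.598793813656026, 3.452776836742295, -12.47822858590748, 5.071095921517893, -12.211055805486051, 16.13465282029803, -16.036744050757164, 13.969158186515886, -17.54389006715111, -20.15337789721001, 7.596771027288003, -15.112588971911077, 7.525243534094905, 3.610916351964711, -7.824599945002772, 5.3902768367422995, -12.478228585907484, 17.595292800847293, -13.629404245150752, 12.778804380633328, -16.036744050757168, 8.15665818651589, 5.047852131172391, 5.3839955951778595, 4.1321162557659195, -12.782947687919092, -5.498851613727171, 5.548416351964711, -11.180448384667473, 16.357019035065797, -6.665728585907482, 17.595292800847297, -16.98525268481545, 7.485455940968633, -15.137547171427768, 8.156658186515887, 3.11035213117239, -8.039398163480937, 6.069616255765919, -12.828840267766227, 17.20776526634766, -17.73730815773524, -7.869594073573155, 16.3570190350658, -17.252425465236882, 14.758595921517895, -16.98525268481545, 7.48545594096863, 6.5549981475663355, -7.723387132478217, 5.0478521311723865, -11.395246603145637, 17.036358454089417, -7.016340267766226, 17.207765266347657, -16.31210428784283, 7.312726323614403, 17.59135779136358, -17.21285850684682, 8.946095921517898, 5.606489513508051, 4.129607501303932, 4.617498147566337, -11.978432451472315, 3.4903974501664927, -11.395246603145637, 17.03635845408942, -17.603037147095623, 14.371068387018259, -16.31210428784283, 7.3127263236144024, 6.025611518273633, -7.11005237294296, 17.673377317522966, 2.76306138285175, -9.29378625735487, 6.5549981475663355, -11.978432451472317, 16.014594329495893, -12.813595042810334, 13.680510014424717, -17.603037147095627, 8.558568387018257, 6.279637910480671, 3.9568778839497014, 4.088111518273635, -11.365097691937061, 3.5093094396091926, -12.02432169183968, 4.350644533585512, 15.553473066480286, -6.165932451472315, 16.014594329495893, -16.169443482475042, 8.387161574760015, -16.703840267766225, 8.558568387018253, 4.342137910480673, -9.4665158747091, 6.025611518273639, -11.36509769193706, 16.033506318938596, -13.442670131504379, 14.185173241203286, -17.393990069092734, -19.576324300063646, 12.705698812992846, -16.16944348247504, 8.387161574760013, 4.988705051227875, -7.321476931975848, 6.279637910480673, -12.8223643143738, 16.99235371659713, -5.552597691937057, 16.033506318938596, -16.798518571169076, 8.891824801538586, -16.494793189763335, 7.87991659983903, 4.697928421181178, -12.554800909442072, 7.837396336423229, 3.0512050512278783, -11.576522250969944, 4.722183229474772, -12.822364314373802, 16.992353716597137, -16.139294571266454, 13.196809439609194, -16.798518571169076, 8.891824801538592, 5.197752129230765, -8.000128719155068, 6.635428421181177, -12.439834718197593, 16.31818624322786, -19.51181200695519, -8.227605863793215, 17.24638010880417, -14.240712754038498, 13.636505276932432, -16.139294571266458, 7.384309439609191, 5.793223627154424, 5.535976361873891, 3.2602521292307607, -12.255174038149168, 5.077973740175278, -12.439834718197593, 16.318186243227856, -15.960718844751456, 13.722349465631813, 16.569988647219382, -17.55688533192521, 8.343156837267733, -15.240097691937061, 7.384309439609192, 3.8557236271544246, -7.887417396784916, 5.1977521292307625, -12.255174038149171, 17.602170619504683, -13.858183157862292, 12.962337803563154, -15.960718844751455, 7.909849465631815, 5.177244262022989, 5.523112064206798, 17.351038107800576, 5.50831505230871, -8.495735879384908, 5.7932236271544255, -11.243265836449613, 16.164494327554266, -6.442674038149166, 17.602170619504676, -17.21403159752699, 7.6689893638984525, -15.061521965422056, 7.909849465631817, 3.2397442620229873, -7.900281694452001, 5.824438367919328, -12.763896731957821, 3.8559036141082186, 2.3173369456898394, -11.243265836449615, 16.164494327554262, -17.029370917478566, 14.765473740175278, -17.21403159752699, 7.668989363898454, 6.6310233535720435, -7.970195853362283, 5.177244262022985, -11.256130134116702, 16.791180566242822, -6.951396731957822, 17.39889106023254, -16.536120612666746, -17.708019719018793, 12.828654230782869, -17.029370917478566, 8.952973740175278, 5.3777106007965045, 4.313140924233757, 4.693523353572045, -12.22524117235638, 3.61978958101708, -11.256130134116704, 16.791180566242822, -17.538093611287216, 14.562194180903141, -16.536120612666743, 7.308047899550296, 6.253521665846157), 16, 16)

dwtReference_db2_HL <- matrix(c(-1.8586680432283567, -0.7164829378648336, -19.141369066191093, 1.4563152979075795, -16.664427389041126, -4.124303742142333, 16.35276975596962, 2.7445963035099505, 12.850120975079466, 2.3295288134029954, 4.1740309225633645, -18.97760723764143, 0.32145971497153525, -18.56955196956938, -3.9155908953257965, 17.045880833928372, 10.311829166530469, -4.5179088502464815, 4.054856985036445, 9.51844545216046, 3.7200688009820144, 9.32724500287062, 2.998485715455873, 1.7597248566649384, 3.1010816529165326, -3.8014933864277625, -10.393109181987992, -5.211667554435194, -12.02567642267187, 3.694713007274247, 9.19992502538811, 6.485657560545544, -7.227335040886058, 4.443946632496893, 7.597855203287843, 7.87421554496775, 4.442912544870847, -5.458147443555228, -9.599099816265216, -8.557972789061699, -11.789325416898366, 1.463891354210098, 12.131465656262064, 1.2675866782607361, 11.104906162557807, 4.5456975730136335, 0.3939630499073452, 4.34679915283025, 3.1426716117202123, -2.8084504701908477, -8.081284334458553, -5.458147443555228, -11.536599816265218, 4.865420969597096, -9.85182541689837, 1.4638913542100953, 11.232268776932663, 7.599238238596035, 7.7490577228931095, 4.545697573013636, -5.418536950092653, -9.73485240750505, -8.48459725972921, -11.714642814481913, 8.989561707758146, -2.047015178293412, -9.599099816265218, 1.5095725299323965, 10.941523022766333, 7.276391354210097, 11.232268776932663, 4.243389798931338, -5.294290716771592, -7.978499306315768, -5.418536950092653, -11.672352407505054, 4.938796498929589, -9.777142814481914, 1.3283579673961716, 11.270389754854476, -8.656251118304992, 0.09212745037952041, 10.941523022766335, 4.439694474880698, 0.645571897603264, 4.243389798931336, -5.294290716771591, -9.535953987321669, -7.875188510427953, -9.734852407505052, 1.5829480592648886, 11.01620562518279, 7.140857967396171, 11.270389754854476, 4.347195337008767, -5.418808387267395, -9.434296471676882, -0.41376111703508106, -5.166928102396737, -9.838261761403967, -8.650139156436289, -11.473453987321669, 1.2931599292367482, 11.957692911489051, 1.5829480592648872, 11.016205625182788, 4.304161088066771, 0.6836928755250762, 4.347195337008769, -5.4188083872673944, -9.536124256057002, -7.750529126341, 12.424964906985359, -3.945845153596281, 4.773254602222508, -9.53595398732167, 1.2931599292367486, 11.05849603215965, 7.91459961960019, 7.660357185518088, 4.304161088066772, -5.128807124474925, -9.734456223326536, -8.774656826932096, -11.473624256056999, 1.4178193133236978, 11.854109963556983, 1.5445001073822513, -7.289132396767345, 4.497688387970518, 7.105659929236747, 11.05849603215965, 4.55875117993549, -5.382991254146611, -8.220035791262625, -5.1288071244749265, -11.671956223326534, 4.648736931726702, -9.536124256056999, 1.4178193133236996, 10.95491308422758, 7.876151667717551, 7.795940120545508, 4.229764220946535, 3.077317604994785, 2.8885019646100654, 4.558751179935491, -5.382991254146613, -9.777490472268532, -7.5854586848102254, -9.734456223326532, 1.2928884920620023, 11.257224183607699, 7.230319313323701, 10.95491308422758, 4.520303228052851, -5.24740831911919, -8.294432658382863, -5.202470017700136, -11.536250196233134, 9.13679552282734, -2.848899955299027, -11.714990472268529, 1.5828897548544734, 11.958089095667566, 1.2928884920620032, 11.257224183607699, 4.3936224339943015, 0.36821620489818496, 4.520303228052851, -5.247408319119192, -9.851887339388764, -7.659121578035435, -9.598750196233134, 1.2536041175366144, 11.15421429288325, 3.7408228797590555, 0.08046014574507332, 11.058892216338169, 7.624540052397302, 7.901375743943, 4.3936224339943, -5.444283795101817, -9.56134833228245, -8.603256758783889, -11.789387339388766, 1.5092268616292634, 12.09379512276097, 1.2536041175366135, 11.15421429288325, 4.518641288835784, 0.36717369372057806, -11.352844165936276, -0.4958207008649056, -5.141972695721701, -8.130574445335101, -5.444283795101818, -11.498848332282451, 4.820136999874909, -9.851887339388764, 1.5092268616292648, 11.19459824343157, 7.585255677871917, 7.798365853218545, 4.518641288835783, -5.4453263062794255, -9.68549951166668, -8.498884006497596, 12.527311680754703, -1.8894024019596576, -7.900935355437119, -9.561348332282451, 1.4642885602102091, 10.941461100275935, 7.321726861629265, 11.19459824343157, 4.229407238207216, -5.2449825864461515, -8.005555590493618, -5.445326306279423, -11.62299951166668, 4.924509752161201, -9.814604941375855, 1.3738242053590408, -7.4418813340885555, 5.323452509419254, 1.464288560210206, 10.941461100275935, 4.485029982299867, 0.6079013641021698, 4.229407238207216, -5.244982586446154, -9.563010271499518, -7.9019778666147245, -9.68549951166668, 1.5686613124965039, 10.978743498288846, 7.186324205359039, 11.270010619552526, 4.302044650958958, -9.349539311156544, 2.865556920475676, 4.485029982299865, -5.204598635897833, -9.852244322128087, -8.600831026110852, -11.500510271499518, 1.2663705730499766, 12.007045807327422, 1.568661312496503, 10.978743498288848, 4.3496273260296405, 0.6833137402231229, 4.302044650958959, -5.380850621630325, -9.522565578191724), 16, 16)

dwtReference_db2_HH <- matrix(c(-12.742785599587728, -6.712595442733291, 8.841305632582447, -16.202611601219008, 15.956406441590387, -14.202685476311764, 3.0639137650775563, 9.15231241926278, -8.863067086755429, 8.93030072152657, -6.818852622537776, 8.976429644575578, -19.401091775593965, 8.459457378386086, -14.138579876223046, 6.63250814291811, -2.319382377842352, 1.4334466693673877, -6.839700261937361, -0.8573725909452161, -6.734280831881477, -2.618785609238134, 3.5133755353117606, -0.48812631648043325, 3.172499229851026, 1.1598782641104903, 4.337208306117221, -4.4450041967790925, 4.850135464334815, -6.584941205388151, -2.638088090790823, 2.480904362760362, -3.418875815004989, -2.3235202207234353, 7.737815042423595, -8.041565371025927, 8.90404985050407, -4.175592463446133, 5.871564238837579, -16.591544531674227, 6.8764583790791685, -16.20487293945463, 8.235635792599902, -15.643099981654707, 4.471398300586832, 8.664268883299393, -5.522245754802505, 8.392548103492777, -14.107495854837731, -6.410124477919933, 12.259898290168769, -4.175592463446134, 6.390715799172882, -16.591544531674227, 14.107306818743869, -16.20487293945463, 4.879787352935203, 7.986945337339393, -8.05279857874257, 8.66426888329939, -3.9647910737966026, 5.935896543157478, -16.85588929118478, 7.0321385456155365, 8.028665106364734, -2.6853897604117836, 13.62156423883758, -15.692347652344829, 4.93895837907917, 5.487672379539469, 4.879787352935202, 8.886142216668793, -4.557843897736669, 12.020117322964092, -3.9647910737966034, 6.4550481034927785, -16.85588929118478, 14.26298698528024, -16.07009979757856, 4.611936353112344, 12.324852076907854, -3.3360711468823703, 4.938958379079166, 8.324369258868868, -5.706909526394199, 8.886142216668796, -4.557843897736668, 6.207617322964092, -13.133139513461305, 13.68589654315748, -15.956692411855382, 5.0946385456155365, 5.62244552141554, 4.611936353112344, 8.974299767277268, -4.363365869520734, 10.568632689874988, 8.47203515788154, -4.1494548453882985, 6.429490656333495, -17.08204077706607, 6.726768883299388, -15.589791073796604, 7.873396543157476, -15.956692411855384, 5.094638545615537, 8.45914240074494, -5.9747605262170564, 8.974299767277266, -4.363365869520734, 5.95759693991564, -13.119527158721409, 4.99715676615684, 3.5676724050535893, -17.082040777066073, 13.95761732296409, -15.589791073796604, 4.517548103492777, 7.673352907138723, -7.4295583337138655, 8.45914240074494, -4.417305845211157, 6.517648206941964, -16.887562748850137, 6.47674850025094, -15.576178719056708, 8.112087449479997, -16.16896569775265, -3.6292568656767505, -2.5564046063324066, 6.102754245197494, 4.517548103492777, 8.57254978646812, -3.934603652707965, 11.814990840409639, -4.417305845211155, 7.036799767277266, -16.887562748850133, 13.707596939915643, -15.57617871905671, 4.756239009815297, 7.461079621241447, -7.491575527217149, 8.72303220441806, -13.808081858715266, -7.831418081033447, 8.57254978646812, -3.9346036527079638, 6.0024908404096395, -13.585654284875856, 14.267648206941963, -15.988365869520731, 4.539248500250939, 6.116366599937394, 4.756239009815295, 8.360276500570848, -3.996620846211248, 12.078880644082762, -4.5749224656991, 6.904093279610764, 7.847626059911036, -5.986355454416057, 6.52164240074494, -16.042305845211157, 8.455148206941967, -15.988365869520731, 4.539248500250938, 8.953063479266792, -5.830457869514103, 8.360276500570848, -3.9966208462112496, 6.266380644082759, -13.7432709053638, 14.134941719275465, -15.720298478969397, 4.448844194798669, 8.906259676804074, -3.543979737967592, 5.099299767277268, 7.641679449473365, -7.98494837907846, 8.953063479266794, -4.273003188508203, 5.903624940235547, -16.52081772554065, 6.785532204418057, -16.1999224656991, 8.322441719275465, -15.720298478969395, 4.448844194798669, 8.760239020163862, -5.579566986732639, 3.600847675641433, 8.68894866079231, -4.48999369807256, 12.308911918931495, -4.273003188508204, 6.422776500570845, -16.52081772554065, 14.01638064408276, -16.1999224656991, 4.966593279610764, 7.909746840024706, -8.075352684530731, 8.760239020163864, -4.022112305726738, 5.887634504962423, -16.75839987021427, 4.716001266764726, 2.972861180889906, -13.441351628172903, 13.653624940235547, -15.621620846211254, 4.84803220441806, 5.492622853295001, 4.966593279610765, 8.808943719354106, -4.580398003524833, 12.116087459828567, -4.022112305726736, 6.406786065297723, -16.758399870214266, 14.230109195207907, -16.14022524188655, -3.5247692938111364, 0.6814392436577443, -15.62162084621125, 4.848032204418061, 8.329319732624402, -5.620103599718635, 8.808943719354106, -4.580398003524833, 6.303587459828564, -13.190460745391434, 13.637634504962422, -15.859202990884869, 5.061760755543208, 5.552320077107547, 4.703179106805137, 8.968484444971043, -10.307673189277427, -7.601492522658267, 8.3293197326244, -4.0626489187127355, 6.3522921590188055, -17.104594882854233, 6.8227390201638665, -15.647112305726736, 7.8251345049624215, -15.85920299088487, 5.061760755543211, 8.389016956436947, -5.883517772524265, 8.968484444971043, -4.4497685672510565, 6.035324680881085), 16, 16)

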