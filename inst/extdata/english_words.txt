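A
ABLE
ABOUT
ABOVE
ACCOUNT
ACID
ACROSS
ACT
ACTION
ADD
AFTER
AGAIN
AGAINST
AGE
AGO
AGREE
AIR
ALL
ALMOST
ALONE
ALONG
ALREADY
ALSO
ALWAYS
AMONG
AMOUNT
AN
AND
ANGER
ANGLE
ANIMAL
ANSWER
ANY
APPEAR
APPLE
AREA
ARM
ARMY
AROUND
ART
AS
ASK
AT
ATTACK
ATTEMPT
AUNT
AUTUMN
AWAY
BABY
BACK
BAD
BAG
BALL
BAND
BANK
BAR
BASE
BASIC
BE
BEAR
BEAT
BEAUTY
BECAUSE
BED
BEE
BEEN
BEFORE
BEGAN
BEGIN
BEHIND
BEING
BELIEVE
BELL
BELONG
BELOW
BEND
BEST
BETTER
BETWEEN
BIG
BILL
BIRD
BIT
BLACK
BLOOD
BLOW
BLUE
BOARD
BOAT
BODY
BONE
BOOK
BOTH
BOTTOM
BOX
BOY
BRAIN
BRANCH
BREAD
BREAK
BRIGHT
BRING
BROAD
BROKE
BROTHER
BROWN
BUILD
BURN
BUSINESS
BUT
BUY
BY
CALL
CAME
CAMP
CAN
CAPITAL
CAR
CARD
CARE
CARRY
CASE
CAT
CATCH
CAUSE
CELL
CENTER
CENTURY
CERTAIN
CHAIR
CHANCE
CHANGE
CHARGE
CHART
CHECK
CHIEF
CHILD
CHILDREN
CHOOSE
CIRCLE
CITY
CLAIM
CLASS
CLEAN
CLEAR
CLIMB
CLOCK
CLOSE
CLOTH
CLOUD
COAT
COLD
COLLECT
COLOR
COLUMN
COME
COMMON
COMPANY
COMPARE
COMPLETE
CONDITION
CONSIDER
CONTAIN
CONTINUE
CONTROL
COOK
COOL
COPY
CORN
CORNER
CORRECT
COST
COULD
COUNT
COUNTRY
COURSE
COVER
CREATE
CROP
CROSS
CROWD
CRY
CURRENT
CUT
DANCE
DARK
DAY
DEAD
DEAL
DEAR
DEATH
DECIDE
DECIMAL
DEEP
DEGREE
DESCRIBE
DESERT
DESIGN
DETAIL
DETERMINE
DEVELOP
DID
DIE
DIFFER
DIFFICULT
DIRECT
DISCOVER
DISCUSS
DISTANT
DIVIDE
DIVISION
DO
DOCTOR
DOES
DOG
DONE
DOOR
DOUBLE
DOWN
DRAW
DREAM
DRESS
DRINK
DRIVE
DROP
DRY
DURING
EACH
EAR
EARLY
EARTH
EASE
EAST
EASY
EAT
EDGE
EFFECT
EGG
EIGHT
EITHER
ELEMENT
ELSE
END
ENEMY
ENERGY
ENGINE
ENOUGH
ENTER
EQUAL
EQUATE
ESPECIALLY
EVEN
EVENING
EVENT
EVER
EVERY
EXACT
EXAMPLE
EXCEPT
EXCITE
EXERCISE
EXPECT
EXPERIENCE
EXPERIMENT
EXPLAIN
EXPRESS
EYE
FACE
FACT
FAIR
FALL
FAMILY
FAMOUS
FAR
FARM
FAST
FAT
FATHER
FAVOR
FEAR
FEED
FEEL
FEET
FELL
FELT
FEW
FIELD
FIG
FIGHT
FIGURE
FILL
FINAL
FIND
FINE
FINGER
FINISH
FIRE
FIRST
FISH
FIT
FIVE
FLAT
FLOOR
FLOW
FLOWER
FLY
FOLLOW
FOOD
FOOT
FOR
FORCE
FOREST
FORM
FORWARD
FOUND
FOUR
FRACTION
FREE
FRESH
FRIEND
FROM
FRONT
FRUIT
FULL
FUN
GAME
GARDEN
GAS
GATHER
GAVE
GENERAL
GENTLE
GET
GIRL
GIVE
GLAD
GLASS
GO
GOLD
GONE
GOOD
GOT
GOVERN
GRAND
GRASS
GREAT
GREEN
GREW
GROUND
GROUP
GROW
GUESS
GUIDE
GUN
HAD
HAIR
HALF
HAND
HAPPEN
HAPPY
HARD
HAS
HAT
HAVE
HE
HEAD
HEAR
HEARD
HEART
HEAT
HEAVY
HELD
HELP
HER
HERE
HIGH
HILL
HIM
HIS
HISTORY
HIT
HOLD
HOLE
HOME
HOPE
HORSE
HOT
HOUR
HOUSE
HOW
HUGE
HUMAN
HUNDRED
HUNT
HURRY
ICE
IDEA
IF
IMAGINE
IN
INCH
INCLUDE
INDICATE
INDUSTRY
INSECT
INSTANT
INSTRUMENT
INTEREST
INTO
INVENT
IRON
IS
ISLAND
IT
ITS
JOB
JOIN
JOY
JUMP
JUST
KEEP
KEPT
KEY
KILL
KIND
KING
KNEW
KNOW
LAND
LANGUAGE
LARGE
LAST
LATE
LAUGH
LAW
LAY
LEAD
LEARN
LEAST
LEAVE
LED
LEFT
LEG
LENGTH
LESS
LET
LETTER
LEVEL
LIE
LIFE
LIFT
LIGHT
LIKE
LIKELY
LINE
LIST
LISTEN
LITTLE
LIVE
LOCATE
LONG
LOOK
LOST
LOT
LOUD
LOVE
LOW
MACHINE
MADE
MAIN
MAJOR
MAKE
MAN
MANY
MAP
MARK
MARKET
MASS
MASTER
MATCH
MATERIAL
MATTER
MAY
MEAN
MEANT
MEASURE
MEAT
MEET
MELODY
MEMBER
MEN
METAL
METHOD
MIDDLE
MIGHT
MILE
MILK
MILLION
MIND
MINE
MINUTE
MISS
MIX
MODERN
MOLECULE
MOMENT
MONEY
MONTH
MOON
MORE
MORNING
MOST
MOTHER
MOTION
MOUNT
MOUNTAIN
MOUTH
MOVE
MUCH
MUSIC
MUST
MY
NAME
NATION
NATURAL
NATURE
NEAR
NECESSARY
NECK
NEED
NEIGHBOR
NEVER
NEW
NEXT
NIGHT
NINE
NO
NOISE
NOON
NOR
NORTH
NOSE
NOT
NOTE
NOTHING
NOTICE
NOUN
NOW
NUMBER
NUMERAL
OBJECT
OBSERVE
OCCUR
OCEAN
OF
OFF
OFFER
OFFICE
OFTEN
OIL
OLD
ON
ONCE
ONE
ONLY
OPEN
OPERATE
OPINION
OR
ORDER
ORGAN
ORIGINAL
OTHER
OUR
OUT
OVER
OWN
OXYGEN
PAGE
PAINT
PAIR
PAPER
PARAGRAPH
PARENT
PART
PARTIAL
PARTY
PASS
PAST
PATTERN
PAY
PEACE
PEOPLE
PER
PERHAPS
PERIOD
PERSON
PHRASE
PICK
PICTURE
PIECE
PITCH
PLACE
PLAIN
PLAN
PLANE
PLANET
PLANT
PLAY
PLEASE
PLURAL
POEM
POINT
POOR
POPULATE
PORT
POSE
POSITION
POSSIBLE
POST
POUND
POWER
PRACTICE
PREPARE
PRESENT
PRESS
PRETTY
PRINT
PROBABLE
PROBLEM
PROCESS
PRODUCE
PRODUCT
PROPER
PROPERTY
PROTECT
PROVE
PROVIDE
PULL
PUSH
PUT
QUART
QUESTION
QUICK
QUIET
QUITE
QUOTIENT
RACE
RADIO
RAIL
RAIN
RAISE
RAN
RANGE
RAPID
RATHER
REACH
READ
READY
REAL
REASON
RECEIVE
RECORD
RED
REGION
REMEMBER
REPEAT
REPLY
REPRESENT
REQUIRE
REST
RESULT
RICH
RIDE
RIGHT
RING
RISE
RIVER
ROAD
ROCK
ROLL
ROOM
ROOT
ROPE
ROSE
ROUND
ROW
RULE
RUN
SAFE
SAID
SAIL
SALT
SAME
SAND
SAT
SAVE
SAW
SAY
SCALE
SCHOOL
SCIENCE
SCORE
SEA
SEARCH
SEASON
SEAT
SECOND
SECTION
SEE
SEED
SEEM
SELECT
SELF
SELL
SEND
SENSE
SENT
SENTENCE
SEPARATE
SERVE
SET
SETTLE
SEVEN
SEVERAL
SHALL
SHAPE
SHARE
SHARP
SHE
SHEET
SHELL
SHINE
SHIP
SHOE
SHOP
SHORE
SHORT
SHOULD
SHOUT
SHOW
SIDE
SIGHT
SIGN
SILENT
SILVER
SIMILAR
SIMPLE
SINCE
SING
SINGLE
SISTER
SIT
SIX
SIZE
SKILL
SKIN
SKY
SLEEP
SLIP
SLOW
SMALL
SMELL
SMILE
SNOW
SO
SOFT
SOIL
SOLDIER
SOLUTION
SOLVE
SOME
SON
SONG
SOON
SOUND
SOUTH
SPACE
SPEAK
SPECIAL
SPEECH
SPEED
SPELL
SPEND
SPOKE
SPOT
SPREAD
SPRING
SQUARE
STAND
STAR
START
STATE
STATION
STAY
STEAD
STEAM
STEEL
STEP
STICK
STILL
STONE
STOOD
STOP
STORE
STORY
STRAIGHT
STRANGE
STREAM
STREET
STRETCH
STRING
STRONG
STUDENT
STUDY
SUBJECT
SUBSTANCE
SUCCESS
SUCH
SUDDEN
SUFFIX
SUGGEST
SUIT
SUMMER
SUN
SUPPLY
SUPPORT
SURE
SURFACE
SURPRISE
SWIM
SYLLABLE
SYMBOL
SYSTEM
TABLE
TAIL
TAKE
TALK
TALL
TEACH
TEAM
TELL
TEMPERATURE
TEN
TERM
TEST
THAN
THAT
THE
THEIR
THEM
THEN
THERE
THESE
THEY
THICK
THIN
THING
THINK
THIRD
THIS
THOSE
THOUGH
THOUGHT
THOUSAND
THREE
THROUGH
THROW
THUS
TIE
TIME
TINY
TIRE
TO
TOGETHER
TOLD
TONE
TOO
TOOK
TOOL
TOP
TOTAL
TOUCH
TOWARD
TOWN
TRACK
TRADE
TRAIN
TRAVEL
TREE
TRIANGLE
TRIP
TROUBLE
TRUCK
TRUE
TRY
TUBE
TURN
TWENTY
TWO
TYPE
UNDER
UNIT
UNTIL
UP
UPON
US
USE
USUAL
VALLEY
VALUE
VARY
VERB
VERY
VIEW
VILLAGE
VISIT
VOICE
VOWEL
WAIT
WALK
WALL
WANT
WAR
WARM
WAS
WASH
WATCH
WATER
WAVE
WAY
WE
WEAR
WEATHER
WEEK
WEIGHT
WELL
WENT
WERE
WEST
WHAT
WHEEL
WHEN
WHERE
WHETHER
WHICH
WHILE
WHITE
WHO
WHOLE
WHOSE
WHY
WIDE
WIFE
WILD
WILL
WIN
WIND
WINDOW
WING
WINTER
WIRE
WISE
WISH
WITH
WOMAN
WOMEN
WON
WONDER
WOOD
WORD
WORE
WORK
WORLD
WOULD
WRITE
WRITTEN
WRONG
WROTE
YARD
YEAR
YELLOW
YES
YET
YOU
YOUNG
YOUR
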